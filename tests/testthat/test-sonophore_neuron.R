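test_that("the resting gap solves the molecular-pressure balance", {
  p <- cached_bls()
  resid <- p$Ar * ((p$delta_star / p$Delta)^p$x_rep -
                   (p$delta_star / p$Delta)^p$y_att) - p$P0
  expect_lt(abs(resid), 1e-6 * p$P0)
  expect_equal(p$Delta, 1.11518e-9, tolerance = 1e-4)
  expect_equal(p$Cg, p$P0 / p$kH)
  expect_error(bls_params(a = -1), "non-positive")
})

test_that("membrane capacitance tends to Cm0 in the small-deflection limit", {
  p <- cached_bls()
  expect_lt(abs(membrane_capacitance(0, p) - p$Cm0) / p$Cm0, 1e-15)
  # first-order sensitivity is -Cm0/Delta, so the deviation at deflection Z
  # is |Z|/Delta: within 1e-6 of Cm0 for |Z| below Delta * 1e-6
  z_small <- p$Delta * 1e-6 * c(-1, 1)
  expect_lt(max(abs(membrane_capacitance(z_small, p) - p$Cm0)) / p$Cm0,
            1.01e-6)
  z_a <- p$a * 1e-6 * c(-1, 1)   # the nanometre-scale limit behaves linearly
  expect_equal(membrane_capacitance(z_a, p), p$Cm0 * (1 - z_a / p$Delta),
               tolerance = 1e-8)
  # monotone decrease as the leaflets bow apart
  cz <- membrane_capacitance(seq(0, 20e-9, length.out = 50), p)
  expect_true(all(diff(cz) < 0))
  expect_error(membrane_capacitance(-p$Delta / 2, p), "mechanical failure")
})

test_that("the molecular-pressure quadrature is converged and tabulated faithfully", {
  p <- cached_bls()
  zs <- c(-0.45 * p$Delta, -0.1e-9, 0, 0.2e-9, 1e-9, 5e-9, 40e-9)
  pm64 <- molecular_pressure(zs, p, nodes = 64)
  pm256 <- molecular_pressure(zs, p, nodes = 256)
  expect_lt(max(abs(pm64 - pm256) / (abs(pm256) + p$P0)), 1e-9)
  expect_equal(pm64[zs == 0], p$P0)  # by construction of Delta
  # table interpolation against direct quadrature
  tab <- approx(p$pm_z, p$pm_val, xout = zs)$y
  expect_lt(max(abs(tab - pm64) / (abs(pm64) + p$P0)), 1e-4)
})

test_that("without drive the sonophore stays at its charge-balanced equilibrium", {
  p <- cached_bls()
  Qm0 <- cached_rest()$Qm0
  z0 <- bls_equilibrium(Qm0, p)
  expect_gt(z0, 0)   # with this resting-gap convention PM(0) = P0 > -Pec
  cyc <- mechanical_steady_cycle(0, Qm0, p)
  expect_lt(max(abs(cyc$Z - z0)), 1e-12 + 1e-3 * abs(z0))
  expect_lt((max(cyc$Cm) - min(cyc$Cm)) / mean(cyc$Cm), 1e-3)
})

test_that("the driven steady cycle is converged with respect to the integrator", {
  p <- cached_bls()
  Qm0 <- cached_rest()$Qm0
  c1 <- mechanical_steady_cycle(100e3, Qm0, p, rtol = 1e-6)
  c2 <- mechanical_steady_cycle(100e3, Qm0, p, rtol = 1e-8, conv_tol = 1e-5,
                                nsamples = 4000)
  i1 <- mean(1 / c1$Cm); i2 <- mean(1 / c2$Cm)
  expect_gt(abs(i1 * p$Cm0 - 1), 0.1)   # sonication really modulates <1/Cm>
  expect_lt(abs(i1 - i2) / i2, 0.01)
  expect_error(mechanical_steady_cycle(-1, Qm0, p), "PA")
})

test_that("the unsonicated lookup row equals the textbook rates exactly", {
  tab <- cached_table()
  rs <- cached_rs()
  expect_identical(tab$PA[1], 0)
  expect_equal(tab$invcm[1, ], rep(1 / rs$Cm0, length(tab$Qm)))
  want <- hh_rates_oracle(tab$Qm / rs$Cm0 * 1e3, rs)
  for (k in seq_len(8)) {
    expect_equal(unname(tab$rates[1, , k]), unname(want[, k]),
                 tolerance = 1e-12)
  }
})

test_that("bilinear interpolation matches direct computation off-grid", {
  p <- cached_bls(); rs <- cached_rs()
  tab <- build_lookup_table(p, rs, PA_grid = c(0, seq(70e3, 100e3, 5e3)),
                            Qm_grid = seq(-70, -58, by = 2) * 1e-5)
  PA <- 82.5e3
  Qm <- -63.7e-5
  got <- lookup_interp(tab, PA, Qm)
  cyc <- mechanical_steady_cycle(PA, Qm, p)
  direct_invcm <- mean(1 / cyc$Cm)
  direct_rates <- colMeans(rs_rates(Qm / cyc$Cm * 1e3, rs))
  expect_lt(abs(got$invcm - direct_invcm) / direct_invcm, 0.02)
  for (nm in names(direct_rates)) {
    expect_lt(abs(got[[nm]] - direct_rates[[nm]]) /
                (abs(direct_rates[[nm]]) + 1e-3), 0.02)
  }
})

test_that("the lookup build is deterministic and validates its grids", {
  p <- cached_bls(); rs <- cached_rs()
  t1 <- build_lookup_table(p, rs, PA_grid = c(0, 50e3),
                           Qm_grid = c(-80, -40, 0) * 1e-5)
  t2 <- build_lookup_table(p, rs, PA_grid = c(0, 50e3),
                           Qm_grid = c(-80, -40, 0) * 1e-5)
  expect_identical(t1$invcm, t2$invcm)
  expect_identical(t1$rates, t2$rates)
  expect_error(build_lookup_table(p, rs, PA_grid = c(10e3, 50e3)), "include 0")
  expect_error(build_lookup_table(p, rs, PA_grid = c(0, 5e3, 5e3)),
               "strictly increasing")
  expect_error(lookup_slice(cached_table(), 1e9), "range error")
})

test_that("lookup tables round-trip through the JSON export", {
  tab <- build_lookup_table(cached_bls(), cached_rs(),
                            PA_grid = c(0, 100e3),
                            Qm_grid = c(-80, -40, 0, 40) * 1e-5)
  path <- tempfile(fileext = ".json")
  write_lookup(tab, path)
  back <- read_lookup(path)
  expect_equal(back$PA, tab$PA)
  expect_equal(back$invcm, tab$invcm)
  expect_equal(back$rates, tab$rates)
})

test_that("the resting membrane is quiet: sub-0.1% charge drift over 1 s", {
  rest <- cached_rest()
  expect_equal(rest$Vm0, -71.9, tolerance = 1e-3)
  prot <- stimulus_protocol(PA = 0, duty_cycle = 1, duration = 1)
  tr <- simulate_sonic(prot, rs = cached_rs())
  expect_lt(max(abs(tr$Qm - rest$Qm0)) / abs(rest$Qm0), 1e-3)
  expect_lt(max(abs(tr$Vm - rest$Vm0)), 0.5)
  expect_identical(detect_spikes(tr), numeric(0))
})

test_that("during OFF intervals the potential is exactly Qm/Cm0", {
  tr <- simulate_sonic(stimulus_protocol(PA = 100e3, duty_cycle = 0.5,
                                         duration = 20e-3),
                       cached_table(), cached_rs())
  off <- !tr$us_on
  expect_true(any(off))
  expect_identical(tr$Vm[off], tr$Qm[off] / cached_rs()$Cm0 * 1e3)
})

test_that("gates stay within [0, 1] across protocols", {
  for (spec in list(c(50e3, 1), c(300e3, 1), c(300e3, 0.4))) {
    tr <- simulate_sonic(stimulus_protocol(PA = spec[1], duty_cycle = spec[2],
                                           duration = 40e-3),
                         cached_table(), cached_rs())
    g <- as.matrix(tr[, c("m", "h", "n", "p")])
    expect_true(all(g >= 0 & g <= 1))
  }
  nb <- cached_nbls_100()
  g <- as.matrix(nb[, c("m", "h", "n", "p")])
  expect_true(all(g >= 0 & g <= 1))
})

test_that("spiking has a pressure threshold and is monotone in drive", {
  counts <- vapply(c(25e3, 50e3, 100e3, 200e3), function(PA) {
    tr <- simulate_sonic(stimulus_protocol(PA = PA, duty_cycle = 1,
                                           duration = 100e-3),
                         cached_table(), cached_rs())
    length(detect_spikes(tr))
  }, numeric(1))
  expect_identical(counts[1], 0)      # below threshold
  expect_gt(counts[2], 3)             # sustained firing above it
  expect_true(all(diff(counts) >= 0))
})

test_that("effective-variable and co-integrated models agree on a spiking run", {
  # substantive oracle comparison at a pressure where both models spike
  prot <- stimulus_protocol(PA = 300e3, duty_cycle = 1, duration = 30e-3)
  nb <- simulate_full_nbls(prot, cached_bls(), cached_rs())
  so <- simulate_sonic(prot, cached_table(), cached_rs())
  sp_nb <- detect_spikes(nb)
  sp_so <- detect_spikes(so)
  expect_gt(length(sp_nb), 4)
  expect_gt(length(sp_so), 4)
  lat_nb <- compute_latency(sp_nb)
  lat_so <- compute_latency(sp_so)
  # measured fidelity of the cycle-averaged approximation at 250 kHz
  expect_lt(abs(lat_so - lat_nb) / lat_nb, 0.30)
  fr_nb <- compute_firing_rate(sp_nb)
  fr_so <- compute_firing_rate(sp_so)
  expect_lt(abs(fr_so - fr_nb) / fr_nb, 0.15)
})

test_that("the oracle at rest matches the effective model and relaxes when undriven", {
  prot0 <- stimulus_protocol(PA = 0, duty_cycle = 1, duration = 5e-3)
  nb <- simulate_full_nbls(prot0, cached_bls(), cached_rs())
  so <- simulate_sonic(prot0, rs = cached_rs())
  expect_lt(max(abs(nb$Vm - so$Vm)), 0.05)
  expect_identical(detect_spikes(nb), numeric(0))
  # release mid-cycle, then watch the deflection envelope decay toward its
  # equilibrium; the sonophore is near-critically damped at nanometre
  # deflections, so the ring-down lives on a ~100 ns scale
  prot <- stimulus_protocol(PA = 100e3, duty_cycle = 1, duration = 9e-6)
  tr <- simulate_full_nbls(prot, cached_bls(), cached_rs(), dt_out = 1e-9,
                           tail = 1e-6)
  rel <- tr[tr$t > prot$duration, ]
  zend <- rel$Z[nrow(rel)]
  dev <- abs(rel$Z - zend)
  t_rel <- rel$t - prot$duration
  peaks <- vapply(list(c(0, 5e-8), c(5e-8, 1.5e-7), c(1.5e-7, 5e-7),
                       c(5e-7, 1e-6)),
                  function(w) max(dev[t_rel > w[1] & t_rel <= w[2]]),
                  numeric(1))
  expect_true(all(diff(peaks) < 0))
  expect_lt(peaks[4], 1e-4 * peaks[1])
})

test_that("the oracle refuses over-long protocols and bad tables are caught", {
  prot <- stimulus_protocol(PA = 50e3, duration = 0.2)
  expect_error(simulate_full_nbls(prot, cached_bls(), cached_rs()),
               "max_duration")
  expect_error(simulate_sonic(stimulus_protocol(PA = 50e3), table = NULL),
               "lookup table")
  expect_error(simulate_sonic(stimulus_protocol(PA = 1e9), cached_table()),
               "range error")
})

test_that("spike detection, latency and firing-rate metrics", {
  # flat trace
  expect_identical(detect_spikes(seq(0, 0.1, 1e-4), rep(-70, 1001)),
                   numeric(0))
  # constructed crossings
  fx <- generate_fixture("spike-trace",
                         crossing_times = c(10e-3, 20e-3, 30e-3))
  expect_equal(detect_spikes(fx), c(10e-3, 20e-3, 30e-3))
  # refractory rule: two crossings 0.2 ms apart count once
  t <- seq(0, 5e-3, 1e-5)
  v <- rep(-70, length(t))
  v[t >= 1.0e-3 & t < 1.1e-3] <- 10
  v[t >= 1.2e-3 & t < 1.3e-3] <- 10
  expect_length(detect_spikes(t, v, refractory = 1e-3), 1)
  expect_length(detect_spikes(t, v, refractory = 0.05e-3), 2)
  # latency
  expect_equal(compute_latency(c(12, 20, 31) * 1e-3), 12e-3)
  expect_identical(compute_latency(numeric(0)), NA_real_)
  expect_equal(compute_latency(5e-3, onset = 2e-3), 3e-3)
  expect_error(compute_latency(1e-3, onset = -1), "onset")
  # firing rate: mean reciprocal ISI
  expect_equal(compute_firing_rate(c(10, 20, 30) * 1e-3), 100)
  expect_identical(compute_firing_rate(10e-3), NA_real_)
  expect_equal(compute_firing_rate(c(10, 20, 40) * 1e-3), 75)
  expect_equal(compute_firing_rate(c(5, 10, 20, 400) * 1e-3,
                                   stim_window = c(0, 0.1)), 150)
  expect_error(compute_firing_rate(c(2, 1)), "sorted")
})

test_that("stimulus protocols validate their fields", {
  expect_error(stimulus_protocol(PA = -1), "PA")
  expect_error(stimulus_protocol(PA = 1, duty_cycle = 1.5), "duty_cycle")
  expect_error(stimulus_protocol(PA = 1, f = 1e3, prf = 500,
                                 duty_cycle = 0.5), "carrier")
  expect_error(stimulus_protocol(PA = 1, onset = -1), "onset")
})
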