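{
  "_comment": "Annotated default configuration. Keys starting with '_' are ignored.",
  "geometry": {
    "_comment": "2D head model: x is the beam direction, pixel size dx_mm; the transducer arc apex sits at apex_x_mm, standoff_mm from the outer skull.",
    "dx_mm": 0.5, "grid_nx": 560, "grid_ny": 560,
    "brain_outer_radius_mm": 85, "standoff_mm": 40,
    "aperture_mm": 64, "roc_mm": 63.2, "apex_x_mm": 25,
    "frequency_khz": 250, "amplitude_kpa": 100,
    "points_per_wavelength": 4
  },
  "media": {
    "_comment": "sound_speed m/s, density kg/m^3, alpha0 dB/(MHz cm)",
    "water": {"sound_speed": 1481, "density": 998, "alpha0": 0.002},
    "skull": {"sound_speed": 2820, "density": 1732, "alpha0": 7.75},
    "brain": {"sound_speed": 1500, "density": 1000, "alpha0": 0.8}
  },
  "solver": {
    "_comment": "window_us is the simulated burst window; on-time = DC * window.",
    "cfl": 0.9, "pml": 20, "absorption_exponent": 1,
    "smoothing_mm": 1, "window_us": 500, "ramp_cycles": 5
  },
  "sweep": {
    "skull_mm": [5.4, 7.6, 10.5],
    "dc": [0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
  },
  "roi": {
    "_comment": "three lateral rows x five axial columns = 15 focal samples",
    "y_rows_mm": [-10.19, -5.56, -0.92], "n_columns": 5,
    "column_spacing_mm": 5, "x_extent_mm": 20, "mirror": false
  },
  "neuron": {
    "rs": {
      "_comment": "regular-spiking cortical point neuron; conductances S/m^2, potentials mV",
      "gNa": 560, "gKd": 60, "gM": 0.75, "gLeak": 0.205,
      "VNa": 50, "VK": -90, "VLeak": -70.3, "VT": -56.2,
      "tau_max": 0.608, "Cm0_uF_cm2": 1
    },
    "table": {
      "_comment": "effective-variable lookup grid; amplitude axis is auto-extended to cover sampled pressures",
      "pa_step_kpa": 25, "qm_min_ncc": -100, "qm_max_ncc": 50,
      "qm_step_ncc": 5, "nsamples": 1000, "rtol": 1e-6
    }
  },
  "protocol": {
    "_comment": "pulsed microscale stimulus: 100 ms at PRF 500 Hz, duty cycle from the sweep",
    "prf_hz": 500, "duration_ms": 100, "dt_out_us": 10,
    "spike_threshold_mv": 0, "refractory_ms": 1
  },
  "output": {"dir": "tfus-out"},
  "seed": 1
}
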