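{
  "_comment": "Named generator presets (reference copy of the constructor defaults). Synthetic stated-world parameters; see ?fate_preset, ?plate_preset_named, ?biopsy_preset_named, ?screen_preset, ?pool_preset.",
  "fate": {
    "colo858_vem": {
      "p_death": 0.60, "p_arrest": 0.20, "p_adapt": 0.20,
      "death_window_h": [24, 48], "reentry_window_h": [48, 84],
      "intermitotic_mean_h": 65, "intermitotic_cv": 0.15,
      "s_g2_duration_h": 10, "untreated_doubling_h": 24,
      "noise_sd": 0.5, "sampling_interval_min": 6, "movie_length_h": 84,
      "geminin_threshold": 2.0
    },
    "mmacsf_vem": {
      "p_death": 0.40, "p_arrest": 0.60, "p_adapt": 0.0,
      "death_window_h": [24, 48],
      "s_g2_duration_h": 10, "untreated_doubling_h": 24,
      "noise_sd": 0.5, "sampling_interval_min": 6, "movie_length_h": 84,
      "geminin_threshold": 1.5
    },
    "colo858_dmso": {
      "untreated_doubling_h": 24, "intermitotic_cv": 0.15,
      "s_g2_duration_h": 10, "noise_sd": 0.5,
      "sampling_interval_min": 6, "movie_length_h": 84,
      "geminin_threshold": 2.0
    }
  },
  "plate": {
    "colo858_seq": {
      "doses_uM": [0, 0.01, 0.032, 0.1, 0.32, 1, 3.2],
      "true_ec50": 0.3, "true_hill": 2, "true_emax": 0.1,
      "initial_count": 2500, "control_doublings": 3,
      "apoptosis_background": 0.05, "replicate_cv": 0.05, "n_replicates": 4,
      "protection_amp": 2.5, "protection_peak_uM": 0.1,
      "protection_width_log10": 0.5
    },
    "mmacsf_seq": {"same_as": "colo858_seq", "protection_amp": 1}
  },
  "screen": {
    "default": {
      "n_compounds": 41, "doses_uM": [0.11, 0.53, 2.67], "n_lines": 3,
      "suppressor_ids": ["cmpd07", "cmpd19", "cmpd33"],
      "suppression_log2": 1.5, "noise_sd": 0.3, "n_replicates": 2
    }
  },
  "biopsy": {
    "ontreat": {"n_cells": 10000, "frac_ngfr_high": 0.30,
                "frac_ki67_high": 0.04, "high_low_separation": 2.5,
                "within_sd": 0.45, "background_frac": 0.05,
                "background_boost": 3},
    "pretreat": {"same_as": "ontreat", "frac_ngfr_high": 0.07,
                 "frac_ki67_high": 0.23}
  },
  "pool": {
    "ngfr_high_pool": {"doubling_h": 32, "initial_count": 1000},
    "ngfr_low_pool": {"doubling_h": 18, "initial_count": 1000}
  }
}
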