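{
  "description": "Five-department bed-allocation case study from a large tertiary hospital (28 departments, 2013 registry): department parameters, fitted quadratic BOR response functions, bed bounds and total budget.",
  "window": {"start": "2013-01-01", "end": "2013-12-31"},
  "total_beds": 644,
  "departments": [
    {
      "name": "W9", "group": "A", "current_beds": 236,
      "observed_bor": 0.752, "observed_discharges": 5478, "admissions": 12712,
      "arrival": {"family": "johnson_sb", "params": [0.025, 0.803, -8.16, 85.98]},
      "median_los": 10, "admit_prob": 0.43,
      "bor_fn": {"beta": 0.721, "a": 0.004, "b": -1.95e-05},
      "lower": 92, "upper": 210,
      "initial_sim_bor": 0.695, "optimal_beds": 166
    },
    {
      "name": "W10", "group": "A", "current_beds": 168,
      "observed_bor": 0.718, "observed_discharges": null, "admissions": null,
      "arrival": {"family": "uniform", "params": [-0.72, 43.75]},
      "median_los": 12, "admit_prob": null,
      "bor_fn": {"beta": 0.895, "a": 0.003, "b": -2.854e-05},
      "lower": 68, "upper": 138,
      "initial_sim_bor": 0.647, "optimal_beds": 121
    },
    {
      "name": "W6", "group": "B", "current_beds": 72,
      "observed_bor": 1.02, "observed_discharges": null, "admissions": null,
      "arrival": {"family": "johnson_sb", "params": [0.289, 0.983, -3.34, 35.11]},
      "median_los": 9, "admit_prob": null,
      "bor_fn": {"beta": 0.687, "a": 0.008, "b": -4.9323e-05},
      "lower": 57, "upper": 140,
      "initial_sim_bor": 0.981, "optimal_beds": 135
    },
    {
      "name": "W27", "group": "B", "current_beds": 114,
      "observed_bor": 1.37, "observed_discharges": null, "admissions": null,
      "arrival": {"family": "uniform", "params": [-3.2, 92.36]},
      "median_los": 5, "admit_prob": null,
      "bor_fn": {"beta": 0.901, "a": 0.003, "b": -2.0066e-05},
      "lower": 114, "upper": 182,
      "initial_sim_bor": 0.985, "optimal_beds": 178
    },
    {
      "name": "W19", "group": "A", "current_beds": 54,
      "observed_bor": 0.70, "observed_discharges": null, "admissions": null,
      "arrival": {"family": "uniform", "params": [-3.2, 92.36]},
      "median_los": 10, "admit_prob": null,
      "bor_fn": {"beta": 0.911, "a": 0.012, "b": -3.054e-04},
      "lower": 30, "upper": 182,
      "initial_sim_bor": 0.689, "optimal_beds": 44
    }
  ]
}
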