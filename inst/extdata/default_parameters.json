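{
  "schema": "asthmod-parameters/1",
  "initial_distribution": {
    "Controlled": 0.20499999999999999,
    "PartiallyControlled": 0.39400000000000002,
    "Uncontrolled": 0.40100000000000002
  },
  "full_adherence_transitions": {
    "Controlled": {
      "Controlled": 0,
      "PartiallyControlled": 0.14999999999999999,
      "Uncontrolled": 0.02,
      "Exacerbation": 0.002
    },
    "PartiallyControlled": {
      "Controlled": 0.10000000000000001,
      "PartiallyControlled": 0,
      "Uncontrolled": 0.070000000000000007,
      "Exacerbation": 0.0060000000000000001
    },
    "Uncontrolled": {
      "Controlled": 0.02,
      "PartiallyControlled": 0.10000000000000001,
      "Uncontrolled": 0,
      "Exacerbation": 0.014999999999999999
    }
  },
  "exacerbation_recovery": {
    "Controlled": 0.20000000000000001,
    "PartiallyControlled": 0.40000000000000002,
    "Uncontrolled": 0.40000000000000002
  },
  "zero_adherence_odds_ratios": {
    "Controlled": 3,
    "PartiallyControlled": 3,
    "Uncontrolled": 3
  },
  "exacerbation_case_fatality": 0.01,
  "admitted_fraction": 0.39000000000000001,
  "utilities": {
    "Controlled": 0.89000000000000001,
    "PartiallyControlled": 0.82999999999999996,
    "Uncontrolled": 0.73999999999999999,
    "ExacerbationAdmitted": 0.33000000000000002,
    "ExacerbationNonAdmitted": 0.56999999999999995
  },
  "utility_adjustment": {
    "age_from": [16, 25, 35, 45, 55, 65, 75],
    "male": [1, 0.98999999999999999, 0.97999999999999998, 0.95999999999999996, 0.93000000000000005, 0.90000000000000002, 0.84999999999999998],
    "female": [0.98999999999999999, 0.97999999999999998, 0.96999999999999997, 0.94999999999999996, 0.92000000000000004, 0.88, 0.82999999999999996]
  },
  "costs": {
    "maintenance_weekly": 8,
    "outpatient_visit": 163,
    "rescue_weekly": {
      "Controlled": 0.29999999999999999,
      "PartiallyControlled": 0.75,
      "Uncontrolled": 1.5,
      "Exacerbation": 0
    },
    "exacerbation_nonadmitted": 150,
    "exacerbation_admitted": 2987
  },
  "outpatient_interval_weeks": {
    "Controlled": 26,
    "PartiallyControlled": 13,
    "Uncontrolled": 4.333333333333333
  },
  "discount_rate_annual": 0.035000000000000003,
  "horizon_years": 20,
  "cycles_per_year": 52,
  "cohort_start_age": 40,
  "sex_mix": 0.5,
  "distributions": {
    "initial_distribution": {
      "family": "dirichlet",
      "params": {
        "Controlled": 82,
        "PartiallyControlled": 157.59999999999999,
        "Uncontrolled": 160.40000000000001
      },
      "mean": {
        "Controlled": 0.20499999999999999,
        "PartiallyControlled": 0.39400000000000002,
        "Uncontrolled": 0.40100000000000002
      }
    },
    "exacerbation_recovery": {
      "family": "dirichlet",
      "params": {
        "Controlled": 40,
        "PartiallyControlled": 80,
        "Uncontrolled": 80
      },
      "mean": {
        "Controlled": 0.20000000000000001,
        "PartiallyControlled": 0.40000000000000002,
        "Uncontrolled": 0.40000000000000002
      }
    },
    "exacerbation_case_fatality": {
      "family": "beta",
      "params": [
        20,
        1980
      ],
      "mean": [
        0.01
      ]
    },
    "admitted_fraction": {
      "family": "beta",
      "params": [
        39,
        61
      ],
      "mean": [
        0.39000000000000001
      ]
    },
    "utilities.Controlled": {
      "family": "beta",
      "params": [
        95.922222222222217,
        11.855555555555554
      ],
      "mean": [
        0.89000000000000001
      ]
    },
    "utilities.PartiallyControlled": {
      "family": "beta",
      "params": [
        129.29555555555558,
        26.482222222222237
      ],
      "mean": [
        0.82999999999999996
      ]
    },
    "utilities.Uncontrolled": {
      "family": "beta",
      "params": [
        157.45555555555558,
        55.32222222222223
      ],
      "mean": [
        0.73999999999999999
      ]
    },
    "utilities.ExacerbationAdmitted": {
      "family": "beta",
      "params": [
        28.855199999999996,
        58.58479999999998
      ],
      "mean": [
        0.33000000000000002
      ]
    },
    "utilities.ExacerbationNonAdmitted": {
      "family": "beta",
      "params": [
        55.312799999999989,
        41.727200000000003
      ],
      "mean": [
        0.56999999999999995
      ]
    },
    "costs.maintenance_weekly": {
      "family": "gamma",
      "params": [
        25,
        0.32000000000000001
      ],
      "mean": [
        8
      ]
    },
    "costs.outpatient_visit": {
      "family": "gamma",
      "params": [
        25,
        6.5199999999999996
      ],
      "mean": [
        163
      ]
    },
    "costs.exacerbation_nonadmitted": {
      "family": "gamma",
      "params": [
        25,
        6
      ],
      "mean": [
        150
      ]
    },
    "costs.exacerbation_admitted": {
      "family": "gamma",
      "params": [
        25,
        119.48
      ],
      "mean": [
        2987
      ]
    },
    "zero_adherence_odds_ratios.Controlled": {
      "family": "lognormal",
      "params": [
        1.0790019320914692,
        0.19804220043536511
      ],
      "mean": [
        3
      ]
    },
    "zero_adherence_odds_ratios.PartiallyControlled": {
      "family": "lognormal",
      "params": [
        1.0790019320914692,
        0.19804220043536511
      ],
      "mean": [
        3
      ]
    },
    "zero_adherence_odds_ratios.Uncontrolled": {
      "family": "lognormal",
      "params": [
        1.0790019320914692,
        0.19804220043536511
      ],
      "mean": [
        3
      ]
    },
    "full_adherence_transitions.Controlled": {
      "family": "dirichlet",
      "params": {
        "PartiallyControlled": 90,
        "Uncontrolled": 12,
        "Exacerbation": 1.2,
        "stay": 496.80000000000007
      },
      "mean": {
        "PartiallyControlled": 0.14999999999999999,
        "Uncontrolled": 0.02,
        "Exacerbation": 0.002,
        "stay": 0.82800000000000007
      }
    },
    "full_adherence_transitions.PartiallyControlled": {
      "family": "dirichlet",
      "params": {
        "Controlled": 60,
        "Uncontrolled": 42.000000000000007,
        "Exacerbation": 3.6000000000000001,
        "stay": 494.39999999999998
      },
      "mean": {
        "Controlled": 0.10000000000000001,
        "Uncontrolled": 0.070000000000000007,
        "Exacerbation": 0.0060000000000000001,
        "stay": 0.82399999999999995
      }
    },
    "full_adherence_transitions.Uncontrolled": {
      "family": "dirichlet",
      "params": {
        "Controlled": 12,
        "PartiallyControlled": 60,
        "Exacerbation": 9,
        "stay": 519
      },
      "mean": {
        "Controlled": 0.02,
        "PartiallyControlled": 0.10000000000000001,
        "Exacerbation": 0.014999999999999999,
        "stay": 0.86499999999999999
      }
    }
  }
}
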