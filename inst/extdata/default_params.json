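{
  "network": {
    "compartments": {
      "sa": {"compliance": 1.8, "unstressed_volume": 420, "intrathoracic": false},
      "sv": {"compliance": 55, "unstressed_volume": 2300, "intrathoracic": false},
      "ra": {"compliance": 10, "unstressed_volume": 20, "intrathoracic": true},
      "pa": {"compliance": 4.5, "unstressed_volume": 50, "intrathoracic": true},
      "pv": {"compliance": 16, "unstressed_volume": 60, "intrathoracic": true}
    },
    "ventricles": {
      "lv": {
        "nominal_gain": 100,
        "elastance_scale": 1.7,
        "unstressed_volume": 15,
        "passive_compliance": 25,
        "relaxation_tau": 0.05,
        "systole_duration": 0.2,
        "activation_peak_frac": 0.7,
        "stenosis_severity": 0,
        "stenosis_scale": 0.068
      },
      "rv": {
        "nominal_gain": 100,
        "elastance_scale": 0.44,
        "unstressed_volume": 20,
        "passive_compliance": 30,
        "relaxation_tau": 0.05,
        "systole_duration": 0.2,
        "activation_peak_frac": 0.7
      }
    },
    "resistors": {
      "mitral": {"resistance": 0.008, "one_way": true, "upstream": "pv", "downstream": "lv"},
      "aortic": {"resistance": 0.01, "one_way": true, "upstream": "lv", "downstream": "sa"},
      "systemic": {"resistance": 0.93, "one_way": false, "upstream": "sa", "downstream": "sv"},
      "venous_return": {"resistance": 0.06, "one_way": false, "upstream": "sv", "downstream": "ra"},
      "tricuspid": {"resistance": 0.012, "one_way": true, "upstream": "ra", "downstream": "rv"},
      "pulmonic": {"resistance": 0.015, "one_way": true, "upstream": "rv", "downstream": "pa"},
      "pulmonary": {"resistance": 0.08, "one_way": false, "upstream": "pa", "downstream": "pv"}
    },
    "respiration": {"mean_itp": -4, "amplitude": 2, "period": 4, "waveform": "sinusoid"},
    "initial_pressures": {"lv": 4.5, "sa": 92, "sv": 5.2, "ra": 3, "rv": 4, "pa": 16, "pv": 6},
    "total_blood_volume": 3767.1
  },
  "control": {
    "maop_setpoint": 106,
    "maop_filter_tau": 2,
    "feedback_gain": 0.2,
    "sy_baseline": 1,
    "sy_range": [0, 8],
    "actuator_tau": 3.5,
    "hr_map": {"base": 70, "slope": 24, "min": 30, "max": 121},
    "inotropic": {"slope": 0.8, "limiter_max": 8},
    "venous": {"k": 150, "sat": 4000, "min_frac": 0.2, "max_frac": 1.5},
    "exercise_setpoint_reset": 30,
    "switches": {"hr": true, "lv_inotropy": true, "rv_inotropy": true, "venous_tone": true},
    "clamps": {}
  }
}
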