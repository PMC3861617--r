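{
  "version": "1.0",
  "reference_concentration_ng_ml": 100,
  "trace_defaults": {
    "baseline": 1.0,
    "center_time": 200,
    "sample_interval": 1.1,
    "duration": 600,
    "noise_sd": 0.02
  },
  "front_speed_um_s": 23.3,
  "ligands": [
    {
      "name": "Wnt3A",
      "kinetic_class": "short",
      "amplitude": 1.2,
      "asymmetry": 0.15,
      "dose_response": { "mode": "negative_cooperative", "y0": 8, "A1": 10, "t1": 150 }
    },
    {
      "name": "Wnt5A",
      "kinetic_class": "short",
      "amplitude": 1.5,
      "asymmetry": 0.15,
      "dose_response": { "mode": "michaelis_menten", "dt_max": 20, "k_half": 67 }
    },
    {
      "name": "Wnt7A",
      "kinetic_class": "long",
      "amplitude": 1.0,
      "asymmetry": 0.30,
      "dose_response": { "mode": "flat", "dt": 27 }
    },
    {
      "name": "Wnt10B",
      "kinetic_class": "long",
      "amplitude": 1.1,
      "asymmetry": 0.30,
      "dose_response": { "mode": "negative_cooperative", "y0": 20, "A1": 12, "t1": 150 }
    },
    {
      "name": "Wnt4",
      "kinetic_class": "very_long",
      "amplitude": 0.9,
      "asymmetry": 0.40,
      "dose_response": { "mode": "negative_cooperative", "y0": 25, "A1": 20, "t1": 200 }
    },
    {
      "name": "Wnt9B",
      "kinetic_class": "very_long",
      "amplitude": 1.3,
      "asymmetry": 0.40,
      "dose_response": { "mode": "negative_cooperative", "y0": 28, "A1": 18, "t1": 180 }
    },
    {
      "name": "Wnt11",
      "kinetic_class": "none",
      "amplitude": 0.0,
      "asymmetry": 0.0,
      "dose_response": { "mode": "flat", "dt": 0 }
    },
    {
      "name": "vehicle",
      "kinetic_class": "none",
      "amplitude": 0.0,
      "asymmetry": 0.0,
      "dose_response": { "mode": "flat", "dt": 0 }
    }
  ]
}
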