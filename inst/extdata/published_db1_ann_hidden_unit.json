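{
  "type": "AnnModel",
  "_comment": "Published hidden-unit combination of the 8:2:1 network trained on the 61 nonpolar enhancers, together with the published min-max scaling maps onto [0.1, 0.9] (stored in printed slope/minimum form). Only one of the two hidden combinations and neither output weight was published, so this fixture carries a single hidden unit and SYNTHETIC placeholder output-layer weights (W_out = 1, b_out = 0); it supports storage and hidden-layer evaluation, not reproduction of the published network's predictions.",
  "input_names": [
    "Hydrogen Bond Acceptor",
    "Polar Surface Area (A2)",
    "Moment of Inertia (g cm2/mol)",
    "Tg (C)",
    "Molar Volume (cm3/mol)",
    "Radius of Gyration (A)",
    "Dipole Moment (debye)",
    "Polarity (J/cm3)^1/2"
  ],
  "W_hidden": [[-22.7143, 31.7314, 32.634, 8.81476, 0.274705, -62.4769, 20.5876, -32.0392]],
  "b_hidden": [23.4289],
  "W_out": [1.0],
  "b_out": 0.0,
  "activation": "sigmoid",
  "output_activation": "linear",
  "input_scaling": {
    "column_names": [
      "Hydrogen Bond Acceptor",
      "Polar Surface Area (A2)",
      "Moment of Inertia (g cm2/mol)",
      "Tg (C)",
      "Molar Volume (cm3/mol)",
      "Radius of Gyration (A)",
      "Dipole Moment (debye)",
      "Polarity (J/cm3)^1/2"
    ],
    "slopes": [0.89, 0.012, 2.8e-5, 5.1e-3, 2.7e-3, 0.087, 0.13, 0.15],
    "mins": [0.2, 12.03, 732.50, -85.95, 175.61, 3.75, 0.66, 0.47],
    "lo": 0.1,
    "hi": 0.9
  },
  "response_scaling": {
    "column_names": ["ER"],
    "slopes": [0.012],
    "mins": [0.63],
    "lo": 0.1,
    "hi": 0.9
  }
}
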