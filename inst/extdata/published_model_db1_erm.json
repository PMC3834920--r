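{
  "type": "SubsetModel",
  "_comment": "Published eight-descriptor linear model for the 61 nonpolar penetration enhancers (hydrocortisone control), selected by the enhanced replacement method. Standard errors and S were not published and are stored as null.",
  "subset": [
    "Hydrogen Bond Acceptor",
    "Polar Surface Area (A2)",
    "Moment of Inertia (g cm2/mol)",
    "Tg (C)",
    "Molar Volume (cm3/mol)",
    "Radius of Gyration (A)",
    "Dipole Moment (debye)",
    "Polarity (J/cm3)^1/2"
  ],
  "intercept": -120.8055,
  "coefficients": [80.4322, -1.7554, -0.0017, -0.1102, -0.0654, 16.9552, -5.0650, 20.6850],
  "std_errors": null,
  "S": null,
  "R2": 0.683,
  "n_obs": 61
}
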