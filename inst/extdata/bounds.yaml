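# Physiologically relevant ranges of the ten layer II stellate cell
# measurements used to validate stochastically generated models. A bound of
# null means the measurement is unconstrained on that side. All comparisons
# are inclusive at the endpoints.
bounds:
- {name: V_RMP, unit: mV,  description: Resting membrane potential,                       lower: -65.0, upper: -60.0}
- {name: V_SD,  unit: mV,  description: SD of membrane potential at rest,                 lower: null,  upper: 0.01}
- {name: Sag,   unit: "",  description: Sag ratio (steady-state over peak deflection),    lower: 0.35,  upper: 0.65}
- {name: R_in,  unit: MOhm, description: Input resistance,                                lower: 35.0,  upper: 65.0}
- {name: Q_R,   unit: "",  description: Resonance strength,                               lower: null,  upper: 3.5}
- {name: f_R,   unit: Hz,  description: Resonance frequency,                              lower: 3.0,   upper: 12.0}
- {name: f_osc, unit: Hz,  description: Perithreshold membrane potential oscillation frequency, lower: 3.0, upper: 12.0}
- {name: N_100, unit: "",  description: Number of APs for a 100-pA 500-ms step,           lower: 0.0,   upper: 0.0}
- {name: N_400, unit: "",  description: Number of APs for a 400-pA 500-ms step,           lower: 7.0,   upper: 16.0}
- {name: V_AP,  unit: mV,  description: Action potential amplitude,                       lower: 75.0,  upper: null}
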