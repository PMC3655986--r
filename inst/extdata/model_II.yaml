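# 12-state two-step-inactivation gating scheme for Nav1.5: Model I plus a
# slow-inactivated tier I21..I24. Entry into the slow tier (I1x -> I2x) is
# the small, nearly voltage-independent rate rho3; exit (I2x -> I1x) is phi3,
# which grows with hyperpolarization and sets the slow component of
# recovery. Slow-tier horizontal rates mirror the fast inactivated tier
# exactly, which makes every added cycle balance without further derived
# rates.
name: model_II
states: [C1, C2, C3, O, I11, I12, I13, I14, I21, I22, I23, I24]
conducting: O
transitions:
  - {from: C1, to: C2, param: alpha1}
  - {from: C2, to: C1, param: beta2}
  - {from: C2, to: C3, param: alpha2}
  - {from: C3, to: C2, param: beta1}
  - {from: C3, to: O, param: alpha3}
  - {from: O, to: C3, derived: beta3}
  - {from: O, to: I14, param: rho2, scale: c, power: -2.5}
  - {from: I14, to: O, param: rho1, scale: c, power: -1.0}
  - {from: I11, to: I12, param: alpha1, scale: c, power: 1.0}
  - {from: I12, to: I13, param: alpha2, scale: c, power: 1.0}
  - {from: I13, to: I14, param: alpha3, scale: c, power: 1.0}
  - {from: I14, to: I13, param: beta2, scale: c, power: -1.0}
  - {from: I12, to: I11, derived: bal1}
  - {from: I13, to: I12, derived: bal2}
  - {from: I11, to: C1, param: phi1}
  - {from: C1, to: I11, param: rho1, scale: c, power: 0.75}
  - {from: I12, to: C2, param: phi1, scale: c, power: -5.0}
  - {from: C2, to: I12, param: rho1, scale: c, power: -0.75}
  - {from: I13, to: C3, param: phi2}
  - {from: C3, to: I13, param: rho1, scale: c, power: 2.0}
  - {from: I11, to: I21, param: rho3}
  - {from: I21, to: I11, param: phi3}
  - {from: I12, to: I22, param: rho3}
  - {from: I22, to: I12, param: phi3}
  - {from: I13, to: I23, param: rho3}
  - {from: I23, to: I13, param: phi3}
  - {from: I14, to: I24, param: rho3}
  - {from: I24, to: I14, param: phi3}
  - {from: I21, to: I22, mirror: [I11, I12]}
  - {from: I22, to: I21, mirror: [I12, I11]}
  - {from: I22, to: I23, mirror: [I12, I13]}
  - {from: I23, to: I22, mirror: [I13, I12]}
  - {from: I23, to: I24, mirror: [I13, I14]}
  - {from: I24, to: I23, mirror: [I14, I13]}
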