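# 8-state fast-inactivation gating scheme for Nav1.5.
#
# Layout: an activation ladder C1 -> C2 -> C3 -> O (forward rates alpha1..3)
# with a parallel inactivated tier I11..I14 whose activation rates are the
# closed-row rates scaled by c. Closed-state inactivation (Cx -> I1x) is
# carried by scaled copies of the saturating rate rho1; recovery exits are
# phi1 (I11 -> C1, the rate-limiting step of recovery) and phi2; open-state
# fast inactivation is the scaled rho2 entry O -> I14. The backward rates
# marked `derived` are cycle-balancing rates computed from microscopic
# reversibility (beta3 on the O -> C3 step and the two inactivated-row
# deactivation steps). Scale exponents were calibrated so that the scheme,
# with the packaged parameters, reproduces the reference kinetics (activation
# and availability midpoints, recovery time constants).
name: model_I
states: [C1, C2, C3, O, I11, I12, I13, I14]
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
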