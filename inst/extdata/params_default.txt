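# Best-fit Nav1.5 model parameters (shared by model_I and model_II).
# Exponential laws: rate(V) = k * exp(V / n), k in 1/ms, n in mV.
# rho1 is sigmoid: g / (1 + exp(-(V + a) / f)).
# c is the dimensionless row-to-row scaling factor.
alpha1.k 9.435
alpha1.n 39.70
alpha2.k 441.1
alpha2.n 6.593
alpha3.k 11.17
alpha3.n 11.64
beta1.k 0.000037
beta1.n -7.770
beta2.k 0.2241
beta2.n -21.13
phi1.k 0.000020
phi1.n -13.07
phi2.k 0.000302
phi2.n -47.08
phi3.k 0.000230
phi3.n -57.21
rho1.g 0.01296
rho1.a 85.62
rho1.f 15.64
rho2.k 1.823
rho2.n 92.78
rho3.k 0.000315
rho3.n 965.2
c.c 2.146
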