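# Reference rate constants of the RyR2 FKBP-regulation model.
# Association rates (k1, k3) in uM^-1 s^-1, all other rates in s^-1;
# alpha is the dimensionless spontaneous background open probability.
k1: 29.0
k_m1: 6.11e-6
k2: 0.03
k_m2: 0.18
k3: 3.3e5
k_m3: 4.2e-4
k4: 0.001
k_m4: 0.25
kC: 480.0
alpha: 0.005
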