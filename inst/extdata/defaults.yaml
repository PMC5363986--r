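alpha_N: 0.144673157
kappa1: 0.6850067106
k_cl: 0.04210861118
mu_N: 0.03890835673
mu_F: 0.08101696792
k3: 8.421722236999999e-06
mu_I1: 0.08101696792
kappa4: 0.0001469892908
alpha_H1: 0.19689163
kappa5: 3.001125704
mu_H1: 0.08101696792
kappa7: 9.0
kappa_psi: 1.5
alpha_H2: 0.03368688895
kappa6: 1.0
mu_H2: 0.01684344447
alpha_P: 0.1157385256
kappa2: 1.094879785
mu_P: 0.08101696792
alpha_D: 0.144673157
kappa3: 0.5480053685
mu_D: 0.08101696792
theta2: 0.75
alpha3: 7.496114253e-05
alpha4: 0.4715879316
mu_B: 6.36e-06
alpha_A: 0.02
mu_A: 0.02
kappa_A: 9.6
c_GC: 0.04686581064
k_rev: 0.05
kappa_GA: 0.5808523653
kappa_GW: 3.181678038
k_CB: 0.003
k_I2: 0.05659090909
rho_APC: 1.0
m: 3.0
'n': 3.0
mu_G: 0.0001
mu_C: 0.0001
mu_I2: 0.0001
gsk_open: no
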