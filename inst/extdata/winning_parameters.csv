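parameter,config,mean,sd
eta1N,6d,1.7E+00,3.6E-01
eta1N,7b,2.3E+00,7.5E-01
eta1N,7d,5.5E+00,1.7E+00
eta1N,8b,2.0E+00,1.4E+00
eta2,6d,2.2E-04,3.4E-05
eta2,7b,1.5E-04,4.1E-05
eta2,7d,2.3E-04,5.92E-05
eta2,8b,3.1E-04,3.9E-05
eta3,6d,3.3E-04,2.3E-04
eta3,7b,6.4E-04,1.2E-04
eta3,7d,7.4E-04,1.2E-04
eta3,8b,6.2E-04,1.3E-04
eta4,6d,4.7E-05,3.1E-05
eta4,7b,3.4E-05,2.2E-05
eta4,7d,3.3E-05,1.7E-05
eta4,8b,8.1E-06,4.5E-06
f_T,6d,1.3E+04,3.3E+03
f_T,7b,1.2E+04,3.7E+03
f_T,7d,1.3E+04,2.6E+03
f_T,8b,1.4E+04,2.1E+03
gamma_T,6d,2.4E-04,6.8E-06
gamma_T,7b,2.1E-04,2.0E-05
gamma_T,7d,2.5E-04,6.8E-06
gamma_T,8b,2.2E-04,8.6E-06
delta1N,6d,3.0E-04,1.9E-03
delta1N,7b,5.9E-06,1.6E-05
delta1N,7d,1.4E-03,3.4E-03
delta1N,8b,1.9E+00,4.1E-01
delta2,6d,3.2E-05,1.1E-05
delta2,7b,5.7E-05,5.1E-06
delta2,7d,1.4E-05,2.83E-06
delta2,8b,7.7E-04,6.4E-05
delta3,6d,1.8E-03,6.3E-04
delta3,7b,1.1E-03,7.2E-05
delta3,7d,1.2E-03,5.9E-05
delta3,8b,8.3E-03,1.1E-03
f_G,6d,1.2E+05,3.6E+04
f_G,7b,5.9E+04,8.7E+03
f_G,7d,1.8E+05,1.7E+04
f_G,8b,7.4E+03,0.0E+00
gamma_G,6d,5.2E-05,2.1E-05
gamma_G,7b,1.0E-04,7.1E-06
gamma_G,7d,3.2E-05,3.7E-06
gamma_G,8b,5.7E-04,4.4E-06
kappa1N,6d,1.0E-10,3.9E-26
kappa1N,7b,1.0E-10,1.4E-26
kappa1N,7d,1.0E-10,3.9E-26
kappa1N,8b,1.0E-10,1.4E-26
kappa2,6d,3.6E-14,7.3E-16
kappa2,7b,2.7E-11,2.5E-13
kappa2,7d,1.1E-14,5.47E-16
kappa2,8b,NA,NA
f_B,6d,9.2E+03,1.5E+03
f_B,7b,1.2E+04,8.0E+02
f_B,7d,1.2E+04,1.8E+03
f_B,8b,5.3E+04,5.5E+04
gamma_B,6d,1.9E-04,1.9E-05
gamma_B,7b,8.7E-05,1.2E-07
gamma_B,7d,7.5E-05,9.7E-06
gamma_B,8b,1.7E-04,5.1E-05
alpha,6d,5.2E-01,3.7E-01
alpha,7b,1.6E-01,6.2E-02
alpha,7d,2.1E-01,9.8E-02
alpha,8b,3.9E-01,2.1E-01
half_life_T_hour,6d,5.6E+00,1.1E+00
half_life_T_hour,7b,7.2E+00,2.0E+00
half_life_T_hour,7d,5.6E+00,1.25E+00
half_life_T_hour,8b,5.41E+00,6.05E-01
half_life_G_hour,6d,3.0E+00,4.4E-01
half_life_G_hour,7b,2.9E+00,5.9E-01
half_life_G_hour,7d,3.0E+00,5.04E-01
half_life_G_hour,8b,3.95E+00,3.05E-02
half_life_B_hour,6d,9.9E+00,1.4E+00
half_life_B_hour,7b,1.7E+01,1.2E+00
half_life_B_hour,7d,2.0E+01,3.9E+00
half_life_B_hour,8b,7.2E+00,1.0E+01
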