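# material=Pb density_g_cm3=11.35
# total mass attenuation coefficients (coherent scattering included),
# transcribed from the standard NIST XCOM-derived compilation (grid >= 0.1 MeV,
# above the Pb K-edge so log-log interpolation is smooth)
E_MeV	mu_over_rho_cm2_g
0.10	5.549
0.15	2.014
0.20	0.9985
0.30	0.4031
0.40	0.2323
0.50	0.1614
0.60	0.1248
0.80	0.0887
1.00	0.0710
1.25	0.0588
1.50	0.05222
2.00	0.04606
3.00	0.04234
4.00	0.04197
5.00	0.04272
6.00	0.04391
8.00	0.04675
10.0	0.04972
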