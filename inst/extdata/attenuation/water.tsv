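# material=water density_g_cm3=1.0
# total mass attenuation coefficients (coherent scattering included),
# transcribed from the standard NIST XCOM-derived compilation
E_MeV	mu_over_rho_cm2_g
0.10	0.1707
0.15	0.1505
0.20	0.1370
0.30	0.1186
0.40	0.1061
0.50	0.09687
0.60	0.08956
0.80	0.07865
1.00	0.07072
1.25	0.06323
1.50	0.05754
2.00	0.04942
3.00	0.03969
4.00	0.03403
5.00	0.03031
6.00	0.02770
8.00	0.02429
10.0	0.02219
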