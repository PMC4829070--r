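# material=CsI density_g_cm3=4.51
# SYNTHETIC approximate grid: total mass attenuation coefficients estimated
# from elemental photoelectric/incoherent/pair systematics (Cs and I weighted
# by mass fraction), accurate to a few percent over 0.1-10 MeV; consistent
# with the reference detection efficiencies of a 1-cm crystal (about 98% at
# 140 keV, about 15% at 4.4 MeV)
E_MeV	mu_over_rho_cm2_g
0.10	2.06
0.15	0.696
0.20	0.351
0.30	0.163
0.40	0.110
0.50	0.0883
0.60	0.0760
0.80	0.0624
1.00	0.0543
1.50	0.0445
2.00	0.0406
3.00	0.0379
4.00	0.0367
5.00	0.0364
6.00	0.0368
8.00	0.0378
10.0	0.0392
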