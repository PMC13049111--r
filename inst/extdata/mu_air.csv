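# Photon mass attenuation (mu/rho) and mass energy-absorption (muen/rho)
# coefficients for dry air (near sea level), NIST-XCOM-style compilation,
# 1-150 keV. The argon K edge carries duplicated grid points.
# density_g_cm3: 0.001205
# edges_keV: 3.2029
energy_keV,mu_over_rho,muen_over_rho
1.0,3606.0,3599.0
1.5,1191.0,1188.0
2.0,527.9,526.2
3.0,162.5,160.1
3.2029,148.5,146.3
3.2029,154.2,152.0
4.0,77.88,76.20
5.0,40.27,39.31
6.0,23.41,22.70
8.0,9.921,9.446
10.0,5.120,4.742
15.0,1.614,1.334
20.0,0.7779,0.5389
30.0,0.3538,0.1537
40.0,0.2485,0.06833
50.0,0.2080,0.04098
60.0,0.1875,0.03041
80.0,0.1662,0.02407
100.0,0.1541,0.02325
150.0,0.1356,0.02496
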