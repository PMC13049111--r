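# Photon mass attenuation (mu/rho) and mass energy-absorption (muen/rho)
# coefficients for copper, NIST-XCOM-style compilation, 1-150 keV.
# The K edge carries duplicated grid points (below-edge row first); the weak
# L1 edge at 1.096 keV is retained as a duplicated pair as well.
# density_g_cm3: 8.96
# edges_keV: 1.0961 8.979
energy_keV,mu_over_rho,muen_over_rho
1.0,10570.0,10490.0
1.0961,8242.0,8185.0
1.0961,9347.0,9282.0
1.5,4418.0,4393.0
2.0,2154.0,2142.0
3.0,748.8,743.0
4.0,347.3,343.8
5.0,189.9,187.0
6.0,118.6,116.6
8.0,52.55,51.19
8.979,38.29,37.14
8.979,278.4,247.8
10.0,215.9,148.4
15.0,74.05,57.88
20.0,33.79,27.88
30.0,10.92,9.349
40.0,4.862,4.163
50.0,2.613,2.192
60.0,1.593,1.290
80.0,0.7630,0.5581
100.0,0.4584,0.3148
150.0,0.2217,0.1172
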