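# Photon mass attenuation (mu/rho) and mass energy-absorption (muen/rho)
# coefficients for aluminium, NIST-XCOM-style compilation, 1-150 keV.
# Absorption edges carry duplicated grid points (below-edge row first).
# density_g_cm3: 2.699
# edges_keV: 1.5596
energy_keV,mu_over_rho,muen_over_rho
1.0,1185.0,1183.0
1.5,402.2,400.1
1.5596,362.1,359.5
1.5596,3957.0,3829.0
2.0,2263.0,2204.0
3.0,788.0,773.8
4.0,360.5,355.5
5.0,193.4,191.3
6.0,115.3,114.0
8.0,50.33,49.64
10.0,26.23,25.59
15.0,7.955,7.487
20.0,3.441,3.094
30.0,1.128,0.8778
40.0,0.5685,0.3601
50.0,0.3681,0.1840
60.0,0.2778,0.1099
80.0,0.2018,0.05511
100.0,0.1704,0.03794
150.0,0.1378,0.02827
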