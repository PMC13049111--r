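# Photon mass attenuation (mu/rho) and mass energy-absorption (muen/rho)
# coefficients for lead, NIST-XCOM-style compilation, 1-150 keV.
# L1-L3 and K edges carry duplicated grid points (below-edge row first).
# M-shell edge structure below 4 keV is smoothed: photons in that range are
# fully absorbed by any realistic filtration before reaching a lead shield.
# density_g_cm3: 11.35
# edges_keV: 13.035 15.20 15.86 88.005
energy_keV,mu_over_rho,muen_over_rho
1.0,5210.0,5197.0
1.5,2356.0,2344.0
2.0,1285.0,1274.0
3.0,1965.0,1913.0
4.0,1251.0,1221.0
5.0,730.4,712.4
6.0,467.2,454.6
8.0,228.7,220.7
10.0,130.6,124.7
13.035,67.01,64.07
13.035,162.1,129.1
15.0,111.6,87.30
15.20,107.8,84.80
15.20,148.5,113.2
15.86,132.2,101.7
15.86,154.8,120.0
20.0,86.36,68.99
30.0,30.32,25.36
40.0,14.36,12.11
50.0,8.041,6.740
60.0,5.021,4.149
80.0,2.419,1.916
88.005,1.910,1.482
88.005,7.683,2.160
100.0,5.549,1.976
150.0,2.014,1.056
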