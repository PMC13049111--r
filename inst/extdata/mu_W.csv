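# Photon mass attenuation (mu/rho) coefficients for tungsten,
# NIST-XCOM-style compilation, 1-150 keV. Tungsten is used only as the
# anode self-filtration material, so muen/rho is not tabulated.
# L1-L3 and K edges carry duplicated grid points (below-edge row first).
# M-shell edge structure (1.8-2.8 keV) is smoothed; that energy range is
# removed by the inherent filtration of any modeled beam.
# density_g_cm3: 19.3
# edges_keV: 10.2068 11.544 12.10 69.525
energy_keV,mu_over_rho,muen_over_rho
1.0,3683.0,
1.5,1643.0,
2.0,3500.0,
3.0,2500.0,
4.0,1400.0,
5.0,775.0,
6.0,448.0,
8.0,189.0,
10.0,96.91,
10.2068,95.69,
10.2068,222.0,
11.544,155.2,
11.544,216.0,
12.10,188.1,
12.10,221.0,
15.0,138.9,
20.0,65.73,
30.0,22.73,
40.0,10.67,
50.0,5.949,
60.0,3.713,
69.525,2.552,
69.525,11.23,
80.0,7.810,
100.0,4.438,
150.0,1.581,
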