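# Default desk-scale pipeline configuration.

[climate]
n_lon = 48
n_lat = 24
land_fraction = 0.25
temp_sensitivity_per_doubling = 3
seed = 1

[vegetation]
n_species = 30
n_years = 50
tau_d_years = 100
phi_rr = 15
eta_ccm = 8
o2_fraction = 0.14
co2_pal = 8

[weathering]
cp_mass_ratio = 350
recycling_ratio = 5
p_conc = 1432
soil_pco2_ppm = 10000
k_e = 6e-8
lithology = "mean"
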