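species,dbh_cm,dbh_sd,height_m,height_sd,crown_base_m,crown_base_sd,crown_width_m,crown_width_sd,plate_volume_m3,plate_volume_sd,plate_mass_kg,plate_mass_sd,delta_u_mean,delta_u_sd,note
spruce,28.60,14.50,19.73,8.18,11.15,0.65,6.54,1.66,4.24,1.72,3407.56,137.51,0.66,0.33,
korean_pine,45.18,11.90,24.30,5.14,12.39,0.62,7.71,2.04,10.02,2.04,1624.99,248.14,0.46,0.38,plate volume/mass columns look swapped or mislabeled (10.02 m^3 with 1624.99 kg); shipped verbatim
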