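zones:
- isolated
- sporadic
- discontinuous
- continuous
seed:
- 42.0
n_lakes_per_zone:
  isolated: 1
  sporadic: 1
  discontinuous: 1
  continuous: 1
area_range_m2:
- 115.0
- 1237000.0
depth_mean_m:
- 0.8
depth_iqr_m:
- 0.7
pco2_mean_ppmv:
- 1044.0
pco2_iqr_ppmv:
- 554.0
pch4_mean_ppmv:
- 20.4
pch4_iqr_ppmv:
- 21.8
doc_mean_mg_l:
- 15.7
doc_iqr_mg_l:
- 7.7
zone_emission_multipliers:
  isolated: 0.75
  sporadic: 0.75
  discontinuous: 1.3
  continuous: 1.3
ice_free_days_by_zone:
  isolated: 170
  sporadic: 165
  discontinuous: 155
  continuous: 150
wind_mean_m_s:
- 3.0
wind_shape:
- 4.0
chamber_noise_sd_ppm:
- 5.0
contamination_rate:
- 0.0
contamination_tau_s:
- 600.0
chamber_k_inflation:
- 3.0
chamber_cv:
- 0.2
cadence_s:
- 300.0
duration_h:
- 2.5
n_chambers_range:
- 1
- 1
chamber_area_m2:
- 0.0755
chamber_va_ratio_m:
- 0.15
seasons:
- spring
- summer
- autumn
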