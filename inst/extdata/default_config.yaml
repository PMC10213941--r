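# Default run configuration (all keys optional; missing keys use these values)
geometry:
  label: Normal            # Normal or A..G picks a reference geometry
  va_length_mm: 8.7
  width_operculum_mm: 1.2
  width_midpoint_mm: 0.8
  spacing_mm: 0.1          # phantom voxel size
membrane:
  area_mm2: 2.031
  perimeter_mm: 5.131
  thickness_um: 60         # sub-micrometre values are flagged as unit slips
  E_MPa: 3
  poisson: 0.3
  shape: ellipse           # or circle (equal-area)
fluid:
  viscosity_pa_s: 1.0e-3
  density_kg_m3: 1000
load:
  p_max_kpa: [10, 100, 150, 200, 250, 300]
  t_peak_s: 0.006
  duration_s: 0.012
  t_obs_s: 0.025
simulation:
  dt_s: 1.0e-5
  alpha: 1                 # effective-lumen factor for the VA radius
  zeta_add: 1              # added damping ratio of the duct-membrane mode
  mode: analytic           # or fem (discrete plate solve on the ellipse)
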