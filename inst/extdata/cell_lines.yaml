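# Cell-line presets for multicellular spheroid growth (days, mm).
# Constants: division times, mean cell radius and initial colony radii of the
# three classical Folkman-Hochberg spheroid lines; prior medians follow the
# convention that the kernel radius spans about six cell diameters and the
# initial-radius prior sits at the first measured colony radius.
# map_estimate: published posterior-mode fits used as reference parameter
# sets for worked examples and forward simulations.
version: 1
cell_lines:
  L-5178Y:
    doubling_time_h: 11.3
    cell_diameter_um: 10.0
    initial_radius_mm: 0.264
    prior_alpha: 1.4
    prior_sigma_k: 0.06
    profile_c: 1.065
    profile_q: 13
    schedule_days: {from: 0, to: 30, by: 2}
    map_estimate: {alpha: 1.7264, sigma_k: 0.0806, sigma_o: 0.0957, sigma_i: 0.2469}
  V-79:
    doubling_time_h: 16.0
    cell_diameter_um: 10.0
    initial_radius_mm: 0.403
    prior_alpha: 1.04
    prior_sigma_k: 0.06
    profile_c: 1.065
    profile_q: 13
    schedule_days: {from: 0, to: 38, by: 2}
    map_estimate: {alpha: 0.3603, sigma_k: 0.0479, sigma_o: 0.0649, sigma_i: 0.3744}
  B-16:
    doubling_time_h: 18.0
    cell_diameter_um: 15.4
    initial_radius_mm: 0.733
    prior_alpha: 0.9
    prior_sigma_k: 0.09
    profile_c: 1.06
    profile_q: 13
    schedule_days: {from: 0, to: 50, by: 2}
    map_estimate: {alpha: 0.3616, sigma_k: 0.0342, sigma_o: 0.0256, sigma_i: 0.7518}
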