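# Default configuration for run_study(): a full desk-scale comparison study
# on synthetic climate. All randomness derives from `seed`.
seed: 42
grid:
  n_rows: 100
  n_cols: 120
  cell_size: 0.1666666666666667   # 10 arcminutes
  origin: [-11.0, 72.0]           # lon, lat of the NW outer corner
climate:
  sea_fraction: 0.25
  noise_correlation_length: 5
observation:
  occupancy_threshold: 0.5
  flip_noise: 0.1
cmp:
  max_scale: 20
  min_valid_fraction: 0.5
  min_cells: 3
null_baseline:
  p: 0.5
  n_replicates: 5
write_grids: false
# Three toy species spanning contrasted bioclimatic strategies. Limits:
# gdd5min_e (degree-days), t_cold_min_s / t_cold_min_e / t_cold_max_e (deg C),
# moisture_min (index).
species:
  boreal_like:
    gdd5min_e: 550
    t_cold_min_s: -32
    t_cold_min_e: -29
    t_cold_max_e: -2
    moisture_min: 0.25
  temperate_like:
    gdd5min_e: 900
    t_cold_min_s: -17
    t_cold_min_e: -14
    t_cold_max_e: 6
    moisture_min: 0.3
  drought_limited_like:
    gdd5min_e: 1400
    t_cold_min_s: -8
    t_cold_min_e: -6
    t_cold_max_e: 12
    moisture_min: 0.45
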