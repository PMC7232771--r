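# Demo run configuration: a three-basin coastal domain with a salinity
# gradient, 25 coastal site samples, and desk-scale dispersal settings.
seed: 42
grid:
  nx: 48
  ny: 20
  cell_size_km: 5
  habitat_depth_limit: 30
  land:
    border: true
    blocks:
      - [15, 17, 1, 9]     # southern peninsula
      - [31, 33, 12, 20]   # northern peninsula
  depth:
    mode: coastal
    slope_m_per_km: 4
    max_depth: 60
currents:
  seed: 7
  components:
    - {type: gyre, center_km: [40, 50], radius_km: 25, amplitude: 0.12}
    - {type: gyre, center_km: [120, 50], radius_km: 30, amplitude: 0.10}
    - {type: gyre, center_km: [200, 50], radius_km: 25, amplitude: 0.10}
    - {type: jet, y_km: 50, width_km: 20, amplitude: 0.08}
    - {type: noise, amplitude: 0.04, smooth: 4}
environment:
  salinity: {axis: x, from: 25, to: 4}
  temperature: {axis: y, from: 16, to: 12}
release:
  months: [4, 5, 6, 7, 8, 9]
  particles_per_cell: 30
  pld_days: 5
  dt_s: 3600
sites:
  count: 25
  n_regions: 5
analysis:
  generations: 64
  symmetrization: mean
  theta_grid: [0.001, 0.002, 0.003]
  n_perm: 9999
demography:
  N: 100
  m: 0.1
  n_loci: 1000
  n_generations: 200
  n_ind_per_site: 20
  missing_rate: 0
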