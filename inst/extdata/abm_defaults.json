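{
  "p_div": 0.125,
  "div_lim": 12,
  "stem_div_prob": 0.05,
  "stem_symmetric_prob": 0.05,
  "n_stem_init": 20,
  "n_prog_init": 80,
  "n_vessels_init": 8,
  "high_migration_rate": 8.3,
  "low_migration_rate": 0.83,
  "p_high_migratory_daughter": 0.05,
  "max_branch_prob": 0.2,
  "senescent_death_prob": 0.1,
  "n_iterations": 300,
  "hours_per_iteration": 6,
  "domain_side": 1,
  "tumor_lattice_n": 50,
  "vessel_lattice_n": 500,
  "oxygen_radius": 100,
  "vegf_radius": 200,
  "tip_speed": 20,
  "anastomosis_radius": 20,
  "hypoxic_div_factor": 0.5,
  "seed": 1
}
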