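{
  "geometry": {
    "arch_radius": 50,
    "desc_length": 400,
    "inner_diameter": 30,
    "wall_thickness": 2,
    "arch_span": 180,
    "device_thickness": 1.75,
    "skeleton_length": 50,
    "skeleton_arc_fraction": 0.5,
    "graft_start_angle": 90,
    "branch_diameter": 10,
    "branch_angles": [100, 115, 130],
    "extension": 50
  },
  "material": {
    "E_aorta_MPa": 1,
    "E_skeleton_MPa": 5,
    "nu": 0.48,
    "polyester_model": "rigid",
    "E_polyester_MPa": 1780
  },
  "load": {
    "pressure_mmHg": 100
  },
  "fluid": {
    "mu": 0.004,
    "rho": 1050
  },
  "waveform": {
    "HR": 75,
    "SV_ml": 53,
    "systolic_fraction": 0.35,
    "reverse_fraction": 0
  },
  "windkessel": {
    "mean_pressure_mmHg": 100,
    "splits": [0.05, 0.05, 0.05, 0.85],
    "pressure_window_mmHg": [80, 120],
    "rp_fraction": 0.05
  },
  "metrics": {
    "path_ds": 1,
    "wss_threshold": 1.7,
    "s_max": 100
  },
  "solver": {
    "preset": "coarse",
    "beam_ds": 2.5,
    "n_deploy": 10,
    "n_release": 10,
    "flow_n_s": 140,
    "flow_n_e": 24,
    "dt": 0.0005,
    "n_cycles": 2,
    "tol_cyclic": 0.01,
    "mesh_n_theta": 12,
    "mesh_ds": 2.5
  },
  "rates": [0, 0.15, 0.3],
  "seed": 1,
  "output_dir": "runs/sweep"
}
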