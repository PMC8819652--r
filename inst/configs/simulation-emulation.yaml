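# Simulation-emulation preset: synthetic Brownian chain ensemble in a
# periodic cubic box, diffusion over the 4.6 ns coherence window with
# finite-size and isotope corrections, cluster statistics at 6 and 7 A,
# per-frame radius of gyration, and the internal-motion EISF.
seed: 1
hydro:
  temperature: 298
  isotope: D2O
  n_residues: 24
trajectory:
  n_chains: 10
  D_t: 15
  box_edge: 100
  dt: 0.1
  n_steps: 200
  window: [0.0, 4.6]
  cutoffs: [6, 7]
  finite_size: true
  isotope_rescale: true
  lattice: cubic
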