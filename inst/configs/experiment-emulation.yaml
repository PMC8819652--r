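# Experiment-emulation preset: synthetic backscattering spectrum at the
# default instrument settings (q 0.2-1.8 1/A, +-30 ueV window, 0.9 ueV FWHM
# resolution), both fit routes, and the scalar hydrodynamics chain at
# 50 mg/mL, 298 K in heavy water.
seed: 1
hydro:
  temperature: 298
  isotope: D2O
  salt_molarity: 0.15
  concentration_mg_ml: 50
  n_residues: 24
  nu_p: 0.7023
  R_g: 13.8
spectrum_truth:
  D_apparent: 17
  D_int: 30
  tau: 0.02
  noise_scale: 0.02
fit:
  mode: both
  solvent: fixed_width
  n_starts: 2
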