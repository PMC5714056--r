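# Example study configuration for read_run_config().
# Keys mirror the arguments of run_config(); "n" is quoted because a bare
# n: key is implicitly boolean under YAML 1.1.
configurations: [1, 2]
"n": 128
spacing_mm: 3
n_slices: 3
slice_mm: 2.5
n_views: 180
N0: 1.0e7
seed: 1
prescription_gy: 10
beamlet_mm: 5
energy_mev: 2
engine: primary
ptvs: [PTV1, PTV2, PTV3]
mar:
  threshold: 1800
  lambda_s: 1
  lambda_c: 10
  max_iter: 200
  tol: 1.0e-4
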