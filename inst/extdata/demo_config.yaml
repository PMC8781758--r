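# Demo pipeline configuration: noiseless paper-shaped synthetic trajectory,
# measurement stress 66 MPa, FEM cross-check at the reference mesh.
generator:
  noise_sd: 0
fem:
  enabled: true
  nx: 126
  ny: 24
seed: 1
output_dir: results/demo
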