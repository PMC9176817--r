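# Example configuration: perturbed standing with platform rotations at the
# fourth magnitude under vestibular loss, short-range stiffness enabled.
# All omitted values fall back to the packaged defaults; units follow the
# printed parameter tables (degrees here, converted to SI internally).
model:
  kind: balance
noise:
  sensory_sd_deg:
    p_q: 0.1
    p_qd: 0.2
    v_q: 0.3
    v_qd: 0.6
task:
  perturbation: rotation
  magnitude_index: 4
  sensory: vestibular_loss
  srs: true
solver:
  seed: 1
  mesh_dt: 0.01
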