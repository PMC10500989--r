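# Default toy benchmark: the 2-D hidden-barrier double well, biased along the
# suboptimal leading CV x, with one auxiliary bias on y and a graded
# MultiThermal schedule on the upper four replicas.
system:
  name: hidden_barrier_2d
cvs:
  leading: x
  auxiliary: [y]
ladder:
  n_replicas: 8
  pace: 1000
  barrier: 30
  multicv_barrier: 3
  temp_max: [400, 450, 500, 600]
  n_T: 20
  temperature: 300
  n_steps: 2000000
analysis:
  basin_a: [-3, 0]
  basin_b: [0, 3]
  discard: 0.1
  n_blocks: 10
  cv: cv_x
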