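# Small demonstration configuration: a reduced synthetic experiment that
# runs the full pipeline in a few seconds.
seed: 42
out_dir: crossdiv_demo_output
simulation:
  n_taxa: 40
  depth_range: [2000, 4000]
  rarefaction_depth: 1000
rarefaction_depth: 1000
rarefaction_iterations: 5
n_perm: 99
nmds_restarts: 3
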