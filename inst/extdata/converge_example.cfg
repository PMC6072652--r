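# small Curveball-vs-swap convergence run (see ?cmd_converge)
model er
kind directed
n_min 50
n_max 80
d_min 3
d_max 6
replicates 3
steps 2000
record_every 100
seed 42
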