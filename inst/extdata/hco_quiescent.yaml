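# Half-center oscillator of two quiescent swim interneurons
# (the sufficient-inhibition configuration; logistic synapses).
kind: network
preset: hco_quiescent
solver:
  duration: 400000
  dt_out: 2
  rtol: 1.0e-7
  atol: 1.0e-9
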