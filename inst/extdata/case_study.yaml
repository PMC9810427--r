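# Six-protein, four-gene case-study system with the first reference
# environment (one stimulated input, one fatal output).
proteins: [input, input, internal, internal, output, output]
genes: 4
environment:
  stimuli: [1]
  essentials: []
  fatals: [6]
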