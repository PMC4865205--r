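# Per-sensor trained parameters for the fvc2002_db2 image set.
C: 0.05
gamma: 1
t: 7
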