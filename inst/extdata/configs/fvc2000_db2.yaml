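# Per-sensor trained parameters for the fvc2000_db2 image set.
C: 0.07
gamma: 2
t: 5
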