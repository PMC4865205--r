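# Per-sensor trained parameters for the fvc2002_db4 image set.
C: 0.03
gamma: 1
t: 6
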