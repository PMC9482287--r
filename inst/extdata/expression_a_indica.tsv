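gene	detected
psbW	1
petE	1
petF	1
atpC	1
atpD	1
HemA	1
HemL	1
HemB	1
HemC	1
HemE	1
HemY	1
chlH	1
DVR	0
por	0
chlG	0
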