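MEME-minimal motif library

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF AP1
1 1 1 17
1 1 17 1
17 1 1 1
1 17 1 1
1 1 1 17
1 17 1 1
17 1 1 1

MOTIF BATF
1 1 1 17
1 1 17 1
17 1 1 1
1 9 9 1
1 1 1 17
1 17 1 1
17 1 1 1

MOTIF IRF4
1 1 17 1
17 1 1 1
17 1 1 1
17 1 1 1
4.5 4.5 4.5 4.5
1 1 1 17
1 1 17 1
17 1 1 1
17 1 1 1
17 1 1 1

MOTIF TBX21
17 1 1 1
1 1 17 1
1 1 17 1
1 1 1 17
1 1 17 1
1 1 1 17
1 1 17 1
17 1 1 1

MOTIF EOMES
17 1 1 1
1 1 17 1
1 1 17 1
1 1 1 17
1 1 17 1
1 1 1 17
1 1 1 17
17 1 1 1

MOTIF TCF7
1 17 1 1
1 1 1 17
1 1 1 17
1 1 1 17
1 1 17 1
1 1 1 17
1 1 1 17
1 17 1 1

MOTIF LEF1
1 17 1 1
1 1 1 17
1 1 1 17
1 1 1 17
1 1 17 1
17 1 1 1
1 1 1 17
1 17 1 1

MOTIF CTCF
1 17 1 1
1 17 1 1
1 1 17 1
1 17 1 1
1 1 17 1
17 1 1 1
1 1 17 1
1 1 17 1

MOTIF SP1
1 1 17 1
1 1 17 1
1 1 17 1
1 1 17 1
1 17 1 1
1 1 17 1
1 1 17 1
1 1 17 1

MOTIF NFYA
1 17 1 1
1 17 1 1
17 1 1 1
17 1 1 1
1 1 1 17
1 17 1 1
17 1 1 1
1 1 17 1

MOTIF ELK1
17 1 1 1
1 17 1 1
1 17 1 1
1 1 17 1
1 1 17 1
17 1 1 1
17 1 1 1
1 1 17 1

MOTIF ZEB1
1 17 1 1
17 1 1 1
1 17 1 1
1 17 1 1
1 1 1 17
1 1 17 1

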