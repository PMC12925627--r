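MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.250000 C 0.250000 G 0.250000 T 0.250000

MOTIF CDEI
letter-probability matrix: alength= 4 w= 8 nsites= 1 E= 0
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667

MOTIF CDEIII
letter-probability matrix: alength= 4 w= 26 nsites= 1 E= 0
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667

MOTIF core41
letter-probability matrix: alength= 4 w= 41 nsites= 1 E= 0
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.016667 0.950000

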