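MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.280000 C 0.220000 G 0.220000 T 0.280000

MOTIF Twi
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.050000 0.850000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.800000 0.100000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.850000 0.050000
 0.100000 0.100000 0.100000 0.700000

MOTIF Tin
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.800000 0.050000 0.100000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.800000 0.100000
 0.050000 0.050000 0.050000 0.850000
 0.100000 0.100000 0.700000 0.100000

MOTIF Mef2
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.100000 0.700000 0.100000 0.100000
 0.050000 0.050000 0.050000 0.850000
 0.850000 0.050000 0.050000 0.050000
 0.800000 0.050000 0.050000 0.100000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.800000 0.050000 0.050000 0.100000
 0.050000 0.050000 0.050000 0.850000

MOTIF Bap
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.050000 0.700000 0.100000 0.150000
 0.050000 0.050000 0.050000 0.850000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.800000 0.100000
 0.050000 0.050000 0.050000 0.850000
 0.100000 0.600000 0.200000 0.100000

MOTIF Bin
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.050000 0.850000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.800000 0.050000 0.100000
 0.700000 0.100000 0.100000 0.100000

MOTIF Zld
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.100000 0.700000 0.100000 0.100000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.100000 0.750000 0.100000

MOTIF Dl
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.800000 0.100000
 0.750000 0.100000 0.050000 0.100000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.750000 0.100000 0.050000 0.100000
 0.100000 0.600000 0.100000 0.200000
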