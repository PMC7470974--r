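>TATA_SYN TATA_SYN
A [ 4 88 4 88 88 88 4 88 ]
C [ 4 4 4 4 4 4 4 4 ]
G [ 4 4 4 4 4 4 4 4 ]
T [ 88 4 88 4 4 4 88 4 ]
>CCAAT_SYN CCAAT_SYN
A [ 4 4 4 88 88 4 4 88 ]
C [ 4 88 88 4 4 4 88 4 ]
G [ 88 4 4 4 4 4 4 4 ]
T [ 4 4 4 4 4 88 4 4 ]
>SP1_SYN SP1_SYN
A [ 4 4 4 4 4 4 4 4 4 ]
C [ 4 4 4 4 88 4 4 4 4 ]
G [ 88 88 88 88 4 88 88 88 88 ]
T [ 4 4 4 4 4 4 4 4 4 ]
>INR_SYN INR_SYN
A [ 4 4 88 4 4 4 ]
C [ 4 88 4 4 4 88 ]
G [ 4 4 4 88 4 4 ]
T [ 88 4 4 4 88 4 ]
>YY1_SYN YY1_SYN
A [ 4 4 4 88 4 4 4 4 ]
C [ 4 88 88 4 4 88 4 4 ]
G [ 88 4 4 4 4 4 4 4 ]
T [ 4 4 4 4 88 4 88 88 ]
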