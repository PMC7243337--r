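>MA0359.1 RAP1 (fixture)
A [ 17 1 17 1 1 1 17 1 17 1 17 1 ]
C [ 1 17 1 17 17 17 1 1 1 17 1 17 ]
G [ 1 1 1 1 1 1 1 1 1 1 1 1 ]
T [ 1 1 1 1 1 1 1 17 1 1 1 1 ]
>MA0403.1 TBF1 (fixture)
A [ 1 1 17 1 1 1 ]
C [ 1 1 1 1 1 1 ]
G [ 1 1 1 17 17 17 ]
T [ 17 17 1 1 1 1 ]
>MA0363.1 REB1 (fixture)
A [ 1 1 17 1 1 1 1 ]
C [ 1 1 1 17 17 17 1 ]
G [ 1 1 1 1 1 1 17 ]
T [ 17 17 1 1 1 1 1 ]
>MA0265.1 ABF1 (fixture)
A [ 1 1 17 1 1 5 5 5 5 17 1 1 17 ]
C [ 1 17 1 17 1 5 5 5 5 1 17 1 1 ]
G [ 1 1 1 1 1 5 5 5 5 1 1 17 1 ]
T [ 17 1 1 1 17 5 5 5 5 1 1 1 1 ]
>ACS ARS-consensus (synthetic fixture)
A [ 1 1 1 1 17 1 1 1 1 1 17 ]
C [ 1 1 1 1 1 1 1 1 1 1 1 ]
G [ 1 1 1 1 1 17 1 1 1 1 1 ]
T [ 17 17 17 17 1 1 17 17 17 17 1 ]
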