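>SYN0001.1 IRF1
A [   7  79  79  79   7   7   7  79  79  79   7 ]
C [   7   7   7   7   7   7   7   7   7   7   7 ]
G [  79   7   7   7  79   7  79   7   7   7  79 ]
T [   7   7   7   7   7  79   7   7   7   7   7 ]
>SYN0002.1 IRF2
A [   7  79  79  79   3   7   7  79  79  79   3 ]
C [   7   7   7   7  47   7   7   7   7   7  47 ]
G [  79   7   7   7  47   7  79   7   7   7  47 ]
T [   7   7   7   7   3  79   7   7   7   7   3 ]
>SYN0003.1 IRF3
A [   7  79  79  79   3   3  79  79  79  25   3 ]
C [   7   7   7   7  47  47   7   7   7  25  47 ]
G [  79   7   7   7  47  47   7   7   7  25   3 ]
T [   7   7   7   7   3   3   7   7   7  25  47 ]
>SYN0004.1 NFKB1
A [   7   7   7   7  79   7   3   7   7   7 ]
C [   7   7   7   7   7   7  47  79  79  79 ]
G [  79  79  79  79   7   7   3   7   7   7 ]
T [   7   7   7   7   7  79  47   7   7   7 ]
>SYN0005.1 RELA
A [   7   7   7  47  25   7   7   7   7   7 ]
C [   7   7   7   3  25   7   7   7  79  79 ]
G [  79  79  79  47  25   7   7   7   7   7 ]
T [   7   7   7   3  25  79  79  79   7   7 ]
>SYN0006.1 REL
A [   3   7   7  47  25  47   7   7   7   7 ]
C [  47   7   7   3  25   3   7   7  79  79 ]
G [  47  79  79  47  25   3   7   7   7   7 ]
T [   3   7   7   3  25  47  79  79   7   7 ]
>SYN0007.1 JUN
A [   7   7  79   3   7   7  79 ]
C [   7   7   7  47   7  79   7 ]
G [   7  79   7  47   7   7   7 ]
T [  79   7   7   3  79   7   7 ]
>SYN0008.1 SP1
A [  10   7   7   7  10   7   7   7  15  10 ]
C [  10   7   7   7  55   7   7   7  10  45 ]
G [  55  79  79  79  25  79  79  79  65  10 ]
T [  25   7   7   7  10   7   7   7  10  35 ]
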