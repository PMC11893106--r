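>MA9001.1	TFAP2C
A  [ 1 97 1 1 1 1 97 97 1 1 ]
C  [ 1 1 97 97 1 1 1 1 1 1 ]
G  [ 97 1 1 1 97 97 1 1 97 1 ]
T  [ 1 1 1 1 1 1 1 1 1 97 ]
>MA9002.1	FOXK2
A  [ 1 1 1 1 1 97 1 1 1 97 ]
C  [ 1 1 1 1 1 1 97 1 1 1 ]
G  [ 1 97 1 1 1 1 1 1 1 1 ]
T  [ 97 1 97 97 97 1 1 97 97 1 ]
>MA9003.1	TCFL5
A  [ 1 97 1 1 1 1 1 1 97 97 ]
C  [ 97 1 97 1 1 1 1 97 1 1 ]
G  [ 1 1 1 97 1 97 1 1 1 1 ]
T  [ 1 1 1 1 97 1 97 1 1 1 ]
>MA9004.1	ZFX
A  [ 97 1 1 1 1 1 1 97 1 1 ]
C  [ 1 1 1 1 97 97 1 1 1 1 ]
G  [ 1 97 97 97 1 1 1 1 97 1 ]
T  [ 1 1 1 1 1 1 97 1 1 97 ]
>MA9005.1	POU6F2
A  [ 97 1 1 1 97 97 97 1 1 97 ]
C  [ 1 1 1 97 1 1 1 1 97 1 ]
G  [ 1 1 97 1 1 1 1 1 1 1 ]
T  [ 1 97 1 1 1 1 1 97 1 1 ]
>MA9006.1	NR6A1
A  [ 1 1 97 97 1 1 1 1 97 97 ]
C  [ 1 97 1 1 1 1 1 97 1 1 ]
G  [ 1 1 1 1 97 97 1 1 1 1 ]
T  [ 97 1 1 1 1 1 97 1 1 1 ]
>MA9007.1	GATA2
A  [ 97 1 97 1 97 97 1 1 1 1 ]
C  [ 1 1 1 1 1 1 1 1 97 97 ]
G  [ 1 97 1 1 1 1 97 1 1 1 ]
T  [ 1 1 1 97 1 1 1 97 1 1 ]
>MA9008.1	MGA
A  [ 1 1 97 1 1 1 1 97 1 1 ]
C  [ 1 97 1 97 1 1 1 1 1 97 ]
G  [ 1 1 1 1 97 1 97 1 1 1 ]
T  [ 97 1 1 1 1 97 1 1 97 1 ]
>MA9009.1	RREB1
A  [ 1 1 1 1 97 97 97 1 1 97 ]
C  [ 97 97 97 97 1 1 1 97 97 1 ]
G  [ 1 1 1 1 1 1 1 1 1 1 ]
T  [ 1 1 1 1 1 1 1 1 1 1 ]
>MA9010.1	DMRT1
A  [ 1 1 97 1 97 1 97 1 1 1 ]
C  [ 1 1 1 1 1 97 1 1 1 1 ]
G  [ 1 97 1 1 1 1 1 1 1 97 ]
T  [ 97 1 1 97 1 1 1 97 97 1 ]
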