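>SFK0001.1 synthetic_forkhead_A
A [  2  1  1  1  1 90  2  3  1 88 ]
C [  3  1  2  2  2  3 90  2  2  4 ]
G [  3 95  2  2  1  2  3  2  2  4 ]
T [ 92  3 95 95 96  5  5 93 95  4 ]
>SFK0002.1 synthetic_forkhead_B
A [  4  2  3  2  3 78  5  2 ]
C [  4  3  5  4  4  8 76  5 ]
G [  6 80  5  4  5  6  5  6 ]
T [ 86 15 87 90 88  8 14 87 ]
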