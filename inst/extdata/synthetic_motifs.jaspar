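>ERE_synthetic synthetic estrogen-response-element-like palindrome (not a database matrix)
A [ 90  2  2  2  2 90  2 25 25  2 90  2  2  2  2 ]
C [  2  2  2  2 90  2 45 25 25  2  2 90  2  2  2 ]
G [  2 90 90  2  2  2 45 25 25 90  2  2  2 90  2 ]
T [  2  2  2 90  2  2  2 25 25  2  2  2 90  2 90 ]
>PPARGRE_synthetic synthetic direct-repeat-1-like element (not a database matrix)
A [ 90  2  2  2  2 90 45 90  2  2  2  2 90 ]
C [  2  2  2  2 90  2 45  2  2  2  2 90  2 ]
G [  2 90 90  2  2  2  2  2 90 90  2  2  2 ]
T [  2  2  2 90  2  2  2  2  2  2 90  2  2 ]
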