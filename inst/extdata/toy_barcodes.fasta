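>AL01-1
ATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGC
>AL01-2
GTGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGC
>AL01-3
ATGAATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGC
>AL01-4
ATGCATGCATGCATGCATGNATGCATGCATGCATGCATGCATGCATGCATGCATGCATGC
>AL02-1
ATGCATGCATGCATGCATGCATGCGCCCGCTCATGCATGCATGCATGCATGCATGCATGC
>AL02-2
ATGCATGCATGCATGCATGCATGCGCCCGCTCATGCATGCATGCGTGCATGCATGCATGC
>AL02-3
ATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGC
>BE01-1
ATGCGGCCGTGCGTGCGTGCATGCATGCATGCGGCCGTGCGTGCATGCGTGCATGCATGC
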