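>IGHV1 role=V
TGTGCAAAA
>IGHV2 role=V
TGTGCAAGA
>IGHV3 role=V
TGTGTTAGA
>IGHD1 role=D
GATTATGGTGGTAATAGTTAT
>IGHD2 role=D
GGTATTACTACTGTTGTT
>IGHD3 role=D
AGTGGTTATGATTATGATTAT
>IGHD8-2 role=D ultralong_core
GGTTATAGTTGTCCTGATGGTTATAGTTATGGTTATTGTAGTTATGGTTATGATAGTTGTTATGGTTATGAATATAGTAG
TTATTGT
>IGHJ1 role=J
TATTTTGATTAT
>IGHJ2 role=J
GCACTGGATTAT
>IGHJ3 role=J
GTTGCATATGTTTATATTTGG
>IGHV1-7-tail role=duplication_tail
ACTACTGTTCATCAA
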