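>ISSN1_region
GTAAGTCTGCCAGCATTATGAAAGTGAATCTT
>ISSN1_target18
CCAGCATTATGAAAGTGA
>ISSN1_target20
CCAGCATTATGAAAGTGAAT
>synthetic_POLR2H_WT
ACTGCATTGTGAGAGTGA
>synthetic_POLR2H_M1
CCAGCATTGTGAGAGTGA
>synthetic_POLR2H_M2
ACTGCATTATGAAAGTGA
>synthetic_POLR2H_M3
CCAGCATTATGAAAGTGA
>synthetic_PITHD1
CGAGCATTGTGAAACTGA
>synthetic_SERPINB7
TGAGCATTGTGAACGTGG
>synthetic_RTTN
CTAGCTTTATGAGAGTGC
>synthetic_REV3L
CCAGTATTATCAAAGCGA
>synthetic_PRKRA
CCTGCATTATGAGAGTCA
>synthetic_GOLGA4
ACAGCGTTATGCAAGTGG
>synthetic_PAK1
ACAGTATTATGGAAGTGC
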