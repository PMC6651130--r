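>tae-miR3117a
UGAGAAAGGACUGCAUCAUCU
>tae-miR3117b
UGAGGAAGGACUGCAUCAUCU
>tae-miR3084a
UAAUCUUCUGGAUACAUGCUUA
>tae-miR5071a
UCAAGCAUCAUAUCAUGGACA
>tae-miR7757a
ACAAAACCUUCAGCUAUCCAUC
>tae-miR9863a
UGAGAAGGUAGAUCAUAAUAGC
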