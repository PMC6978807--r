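>mmu-miR-411-5p
UAGUAGACCGUAUAGCGUACG
>mmu-miR-376b-3p
AUCAUAGAGGAACAUCCACUU
>mmu-miR-3099-3p
UAGGCUAGAGAGAGGUUGGGC
>mmu-miR-381-3p
UAUACAAGGGCAAGCUCUCUGU
>mmu-miR-421-3p
AUCAACAGACAUUAAUUGGGCGC
>mmu-miR-378a-3p
ACUGGACUUGGAGUCAGAAGG
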