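>hsa-let-7a-5p example mature sequence
UGAGGUAGUAGGUUGUAUAGUU
>hsa-miR-16-5p example mature sequence
UAGCAGCACGUAAAUAUUGGCG
>hsa-miR-25-3p example mature sequence
CAUUGCACUUGUCUCGGUCUGA
>hsa-miR-181a-5p example mature sequence
AACAUUCAACGCUGUCGGUGAGU
>hsa-miR-181b-5p example mature sequence
AACAUUCAUUGCUGUCGGUGGGU
>hsa-miR-181d-5p example mature sequence
AACAUUCAUUGUUGUCGGUGGGU
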