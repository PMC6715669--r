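>hsa-let-7a-5p mature miRNA
UGAGGUAGUAGGUUGUAUAGUU
>hsa-miR-17-5p mature miRNA
CAAAGUGCUUACAGUGCAGGUAG
>hsa-miR-21-3p mature miRNA
CAACACCAGUCGAUGGGCUGU
>hsa-miR-200c-3p mature miRNA
UAAUACUGCCGGGUAAUGAUGGA
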