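!version date: 2026/01/01
!description: Synthetic Pfam-to-GO cross-references for examples and tests
Pfam:PF00001.21 RibProtL1 > GO:translation ; GO:0006412
Pfam:PF00001 RibProtL1 > GO:structural constituent of ribosome ; GO:0003735
Pfam:PF00002 RibProtS7 > GO:translation ; GO:0006412
Pfam:PF00003 GTPase_EFTu > GO:GTPase activity ; GO:0003924
Pfam:PF00004 DNA_gyrA > GO:DNA topological change ; GO:0006265
Pfam:PF00005 RNApol_beta > GO:DNA-templated transcription ; GO:0006351
Pfam:PF00006 SecY > GO:protein transport ; GO:0015031
Pfam:PF00007 Orphan_dom > GO:molecular_function ; GO:0003674
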