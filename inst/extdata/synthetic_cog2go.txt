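!version date: 2026/01/01
!description: Synthetic COG-to-GO cross-references for examples and tests
COG:COG0081 RibL1 > GO:translation ; GO:0006412
COG:COG0049 RibS7 > GO:translation ; GO:0006412
COG:COG0050 EFTu > GO:GTPase activity ; GO:0003924
COG:COG0188 GyrA > GO:DNA topological change ; GO:0006265
COG:COG0085 RpoB > GO:DNA-templated transcription ; GO:0006351
COG:COG0201 SecY > GO:protein transport ; GO:0015031
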