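# COG	func	name (synthetic definitions for examples and tests)
COG0081	J	Ribosomal protein L1
COG0049	J	Ribosomal protein S7
COG0050	J	Translation elongation factor EF-Tu
COG0188	L	DNA gyrase subunit A
COG0085	K	DNA-directed RNA polymerase beta subunit
COG0201	U	Preprotein translocase subunit SecY
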