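# Variant (non-canonical) polyadenylation-signal hexamers, DNA alphabet.
# Default list: 16 common single/double-substitution variants of AATAAA
# reported at mouse polyA sites. Edit freely and pass the file to
# variant_pas(); the canonical AATAAA/ATTAAA pair is handled separately.
AGTAAA
TATAAA
CATAAA
GATAAA
AATATA
AATACA
AATAGA
AAAAAG
AAGAAA
ACTAAA
AATGAA
TTTAAA
AAAATA
GGGGCT
ATTACA
AACAAA
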