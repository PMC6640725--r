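raw	canonical	reason
FASG	FASG	Printed in the necroptosis list; plausibly FASLG (death-receptor ligand, apoptosis list) or FAS, but FAS already appears in the same row and merging into FASLG breaks the published 390-91=299 membership arithmetic. Kept verbatim as its own symbol; flagged as a source-table ambiguity.
ANAX1	ANXA1	Spelling used in the source study's prose for annexin A1; the fold-change tables print ANXA1.
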