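lipid_resistance_literature	Lipid-metabolism enzymes implicated in cancer drug resistance (curated review list; user-editable)	ACLY	ACACA	ACACB	FASN	CPT1A	CPT1B	CPT1C	CPT2	SCD
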