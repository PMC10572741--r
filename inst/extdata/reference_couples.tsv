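name	e_ref_mV	pH_ref	m	n	note
NADH	NA	7	1	2	fill e_ref_mV from your preferred compilation (mV vs SHE)
FMN	NA	7	2	2	fill e_ref_mV from your preferred compilation (mV vs SHE)
riboflavin	NA	7	2	2	fill e_ref_mV from your preferred compilation (mV vs SHE)
acetaldehyde	NA	7	1	2	fill e_ref_mV from your preferred compilation (mV vs SHE)
anthraquinone	NA	7	2	2	fill e_ref_mV from your preferred compilation (mV vs SHE)
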