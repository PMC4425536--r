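# Matched tumor-tissue / plasma variant calls (protein level) for 15
# colorectal cancer patients, one row per sample and gene; empty = no call.
sample_id	gene	tumor	plasma
DS1	KRAS
DS1	NRAS
DS1	BRAF
DS3	KRAS	G12S,G12D
DS3	NRAS	G12S
DS3	BRAF
DS4	KRAS
DS4	NRAS
DS4	BRAF
DS6	KRAS	G13D	G12S,G13D
DS6	NRAS
DS6	BRAF
DS8	KRAS	G12V	G12V
DS8	NRAS
DS8	BRAF
DS9	KRAS	G12S,A59E
DS9	NRAS	G12S,Q61*
DS9	BRAF
DS22	KRAS
DS22	NRAS
DS22	BRAF	V600E	V600E
DS23	KRAS
DS23	NRAS
DS23	BRAF
DS24	KRAS
DS24	NRAS
DS24	BRAF
DS25	KRAS	G12S	G12S
DS25	NRAS
DS25	BRAF
DS28	KRAS
DS28	NRAS	A146V,A146A
DS28	BRAF
DS29	KRAS
DS29	NRAS	G12S,G12D,Q61K
DS29	BRAF
DS30	KRAS	G12S	G12S
DS30	NRAS
DS30	BRAF
DS32	KRAS	G12V	G12V
DS32	NRAS
DS32	BRAF
DS33	KRAS
DS33	NRAS
DS33	BRAF
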