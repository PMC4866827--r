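sample	barcode
S1	ACGTGCAT
S2	TGCAGTAC
S3	GATCCGTA
S4	CTAGTCGA
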