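sample_id	group
RC1	RC
RC2	RC
RC3	RC
RM1	RM
RM2	RM
RM3	RM
HC1	HC
HC2	HC
HC3	HC
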