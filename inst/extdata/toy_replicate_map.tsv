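run_id	sample_id
S1_r1	S1
S1_r2	S1
S1_r3	S1
S2_r1	S2
S2_r2	S2
S2_r3	S2
S3_r1	S3
S3_r2	S3
S3_r3	S3
S4_r1	S4
S4_r2	S4
S4_r3	S4
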