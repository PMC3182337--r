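sample_id	subject_id	time_hours
subj1_t0.0	subj1	0
subj1_t4.0	subj1	4
subj1_t24.0	subj1	24
subj2_t0.0	subj2	0
subj2_t0.5	subj2	0.5
subj2_t4.0	subj2	4
subj3_t0.0	subj3	0
subj3_t0.5	subj3	0.5
subj4_t0.0	subj4	0
subj4_t0.5	subj4	0.5
subj5_t0.0	subj5	0
subj5_t0.5	subj5	0.5
subj6_t0.0	subj6	0
subj6_t0.5	subj6	0.5
subj6_t24.0	subj6	24
subj7_t0.0	subj7	0
subj7_t0.5	subj7	0.5
subj8_t0.0	subj8	0
subj8_t4.0	subj8	4
subj8_t24.0	subj8	24
subj9_t0.0	subj9	0
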