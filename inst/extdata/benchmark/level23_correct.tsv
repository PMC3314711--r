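level1	expert_n	level2_correct	level3_correct
Allergy	12	11	9
Autoimmunity	59	58	48
Infectious Disease	104	98	91
Transplantation	9	NA	8
Cancer	45	NA	32
HIV	35	NA	NA
Other	23	19	19
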