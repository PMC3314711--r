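category	n	flat_auc	hier_auc
Beta-Amyloid	213	0.994	0.998
Diabetes	443	0.997	0.998
General Autoimmune	1311	0.967	0.987
Lupus	704	0.975	0.988
Multiple Sclerosis	957	0.982	0.990
Myasthenia Gravis	221	0.983	0.992
Rheumatoid Arthritis	501	0.983	0.990
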