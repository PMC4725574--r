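contrast_id	description	a	b	c	d	published_or	published_p_two
turner_cases_vs_population	45,X carriers: female depression cases vs live-born female newborns	3	2194	3	17035	7.76	0.023
upd_cases_vs_population	whole-chromosome isodisomy: all cases vs population controls	3	3103	2	2697	1.30	1.00
large_all_cases_vs_screened	large (>1 Mb) CNV carriers: cases vs screened controls	74	2649	4	344	2.40	0.10
large_all_cases_vs_population	large CNV carriers: cases vs population controls	74	2649	45	2314	1.44	0.063
large_del_cases_vs_screened	large deletion carriers: cases vs screened controls	20	2703	2	346	1.28	1.00
large_del_cases_vs_population	large deletion carriers: cases vs population controls	20	2703	13	2346	1.34	0.49
large_dup_cases_vs_screened	large duplication carriers: cases vs screened controls	54	2669	2	346	3.46	0.084
large_dup_cases_vs_population	large duplication carriers: cases vs population controls	54	2669	32	2327	1.45	0.10
psychotic_all_vs_screened	large CNV carriers: psychotic-symptom cases vs screened controls	5	136	4	344	3.16	0.13
psychotic_del_vs_screened	large deletion carriers: psychotic-symptom cases vs screened controls	0	141	2	346	0	0.51
psychotic_dup_vs_screened	large duplication carriers: psychotic-symptom cases vs screened controls	5	136	2	346	6.36	0.023
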