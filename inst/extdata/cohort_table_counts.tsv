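group	characteristic	level	count
non_obese	total	all	173672
obese	total	all	4108
non_obese	genetic_risk	high	34502
non_obese	genetic_risk	intermediate	104176
non_obese	genetic_risk	low	34994
obese	genetic_risk	high	1054
obese	genetic_risk	intermediate	2492
obese	genetic_risk	low	562
non_obese	lifestyle	poor	24347
non_obese	lifestyle	intermediate	116339
non_obese	lifestyle	healthy	32986
obese	lifestyle	poor	697
obese	lifestyle	intermediate	2849
obese	lifestyle	healthy	562
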