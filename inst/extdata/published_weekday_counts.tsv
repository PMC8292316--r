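weekday	before_all	before_all_4h	before_morning	before_morning_4h	before_evening	before_evening_4h	after_all	after_all_4h	after_morning	after_morning_4h	after_evening	after_evening_4h
Sunday	463	423	148	130	127	119	481	420	150	134	136	113
Monday	485	440	154	137	143	127	461	424	148	134	130	122
Tuesday	479	440	147	134	142	131	474	434	150	138	135	126
Wednesday	496	460	149	140	155	144	474	433	148	137	128	118
Thursday	471	428	147	137	143	131	478	431	144	130	133	125
Friday	473	436	152	138	135	126	481	426	144	133	147	126
Saturday	444	397	130	111	124	115	470	419	141	125	141	130
Total	3311	3024	1027	927	969	893	3319	2987	1025	931	950	860
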