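variable,overall,cluster_1,cluster_2,cluster_3,cluster_4,cluster_5,cluster_6,cluster_7,cluster_8,cluster_9
n,82577,6785,7770,4142,29989,7697,8634,4911,6143,6506
male,44456,3269,3500,2592,15877,4864,3906,3444,3753,3251
female,38103,3516,4270,1549,14098,2833,4726,1467,2389,3255
medicaid,45675,2504,4687,2743,15519,5697,2262,3571,4096,4596
medicare,20813,2303,1585,704,8344,1026,4236,550,1023,1042
white_or_caucasian,53672,5184,4681,2790,18132,5497,5961,3340,3725,4362
black_or_african_american,17050,755,1829,762,7210,1122,1840,778,1367,1387
hispanic_or_latino,14479,890,1617,751,5740,1324,901,956,1275,1025
ed_discharge,44135,3253,3686,2550,14874,4983,2951,3374,4052,4412
ed_admit,34214,3197,3799,1373,13929,1792,5472,1243,1788,1621
alcohol_related_disorders,28233,1702,2455,1602,9220,3360,2244,2144,1901,3605
delirium_dementia,9487,508,595,349,3829,589,2069,354,440,754
hiv_infection,4140,142,271,181,1892,261,386,191,359,457
impulse_control_disorders,1063,36,165,50,392,113,50,51,60,146
miscellaneous_mental_health,12911,763,1230,585,4651,1094,1667,609,712,1600
mood_disorders,48944,3306,4425,2322,17470,5269,5530,2586,3140,4896
personality_disorders,9023,514,750,500,2593,1267,845,608,511,1435
schizophrenia,15233,683,1143,801,4986,2108,1964,925,934,1689
screening_history_mental_health,51081,2948,4787,2500,19106,4979,5847,2673,3501,4740
suicide_or_self_harm,23061,1095,1838,1349,6672,3851,1604,1635,1533,3484
substance_use_disorders,63413,4024,6001,3284,22846,6679,6052,3848,4810,5869
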