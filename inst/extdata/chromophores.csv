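wavelength_nm,mua_melanosome,mua_blood_oxy,mua_blood_deoxy,mua_bilirubin_per_mgdl,mua_baseline
395,14.8893,39.4745,13.4541,0.00107794,0.015
400,14.2786,49.1146,19.1799,0.00143621,0.015
405,13.6999,57.4123,25.9844,0.00187014,0.015
410,13.1515,63.0502,33.4448,0.00237991,0.015
415,12.6312,65.05,40.8907,0.00295989,0.015
420,12.1373,63.0502,47.4856,0.00359766,0.015
425,11.6683,57.4124,52.3747,0.00427362,0.015
430,11.2226,49.1147,54.8644,0.00496136,0.015
435,10.7988,39.4747,54.5841,0.00562906,0.015
440,10.3955,29.8094,51.5766,0.00624167,0.015
445,10.0116,21.1527,46.2872,0.00676388,0.015
450,9.64598,14.1076,39.4558,0.00716343,0.015
455,9.2975,8.8473,31.948,0.0074144,0.015
460,8.96521,5.22203,24.5771,0.0075,0.015
465,8.6482,2.90676,17.9679,0.0074144,0.015
470,8.34561,1.53273,12.4906,0.00716343,0.015
475,8.05664,0.773507,8.26527,0.00676388,0.015
480,7.78056,0.382406,5.21728,0.00624167,0.015
485,7.51664,0.194504,3.15569,0.00562906,0.015
490,7.26425,0.110556,1.84711,0.00496136,0.015
495,7.02277,0.0767598,1.07025,0.00427362,0.015
500,6.79163,0.068731,0.646614,0.00359766,0.015
505,6.57028,0.083862,0.451112,0.00295989,0.015
510,6.35822,0.143089,0.40961,0.00237991,0.015
515,6.15497,0.296877,0.489372,0.00187014,0.015
520,5.96009,0.618442,0.685752,0.00143621,0.015
525,5.77316,1.16125,1.00612,0.00107794,0.015
530,5.59378,1.88318,1.45182,0.000790676,0.015
535,5.42158,2.59705,2.00104,0.000566804,0.015
540,5.25621,3.03066,2.5983,0.000397098,0.015
545,5.09734,2.99845,3.15687,0.000271889,0.015
550,4.94466,2.56074,3.57677,0.000181935,0.015
555,4.79787,2.0314,3.77365,0.000118979,0.015
560,4.6567,1.81081,3.70693,7.60423e-05,0.015
565,4.52088,2.12224,3.39428,4.74974e-05,0.015
570,4.39016,2.79295,2.90515,2.89944e-05,0.015
575,4.26432,3.3008,2.33664,1.72977e-05,0.015
580,4.14313,3.17976,1.78309,1.00854e-05,0.015
585,4.02638,2.43417,1.31226,5.74681e-06,0.015
590,3.91387,1.48624,0.955808,3.2003e-06,0.015
595,3.80542,0.749146,0.713507,1.74175e-06,0.015
600,3.70084,0.347907,0.565293,9.26424e-07,0.015
605,3.59997,0.188979,0.484136,4.81575e-07,0.015
610,3.50264,0.143891,0.445117,2.44652e-07,0.015
615,3.40871,0.136697,0.429579,1.21468e-07,0.015
620,3.31802,0.138559,0.425525,5.89395e-08,0.015
625,3.23045,0.141717,0.426157,2.79499e-08,0.015
630,3.14586,0.144598,0.428024,1.29534e-08,0.015
635,3.06413,0.146923,0.429547,5.86703e-09,0.015
640,2.98514,0.148621,0.430065,2.59706e-09,0.015
645,2.90877,0.149653,0.429334,1.12351e-09,0.015
650,2.83493,0.15,0.42728,4.75007e-10,0.015
655,2.76351,0.149653,0.423902,1.9627e-10,0.015
660,2.6944,0.148621,0.419232,7.9257e-11,0.015
665,2.62753,0.146923,0.413321,3.12789e-11,0.015
670,2.5628,0.144596,0.406236,1.20641e-11,0.015
675,2.50013,0.141686,0.398057,4.54746e-12,0.015
680,2.43944,0.13825,0.388874,1.67522e-12,0.015
685,2.38064,0.134355,0.378787,6.03124e-13,0.015
690,2.32368,0.130074,0.367902,2.12212e-13,0.015
695,2.26848,0.125484,0.356333,7.29733e-14,0.015
700,2.21497,0.120665,0.344194,2.45238e-14,0.015
705,2.16309,0.115696,0.331604,8.05454e-15,0.015
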