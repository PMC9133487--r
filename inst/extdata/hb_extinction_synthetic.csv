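# Synthetic hemoglobin extinction table (whole blood, 150 g/L Hb).
# Smooth analytic approximation to the canonical visible-band Hb/HbO2
# extinction compilations, built from anchor molar extinctions and natural
# cubic spline interpolation to 1 nm; NOT a measured dataset.
# mu_a = ln(10) * eps * C (C = 2.326 mM), units mm^-1.
# mu_s: Mie-like power law ~ (lambda/500)^-1.2, units mm^-1.
# Columns: lambda_nm, mu_a_hbo2, mu_a_hb, mu_s_hbo2, mu_s_hb
lambda_nm,mu_a_hbo2,mu_a_hb,mu_s_hbo2,mu_s_hb
450,33.7355,55.1549,45.3909,49.93
451,32.6189,53.5756,45.2702,49.7972
452,31.5082,51.9913,45.15,49.665
453,30.4096,50.3973,45.0304,49.5335
454,29.329,48.7886,44.9114,49.4026
455,28.2725,47.1603,44.793,49.2723
456,27.2461,45.5077,44.6752,49.1427
457,26.2557,43.8257,44.5579,49.0137
458,25.3075,42.1095,44.4412,48.8853
459,24.4073,40.3542,44.325,48.7575
460,23.5613,38.5549,44.2094,48.6303
461,22.7738,36.7111,44.0943,48.5038
462,22.042,34.8397,43.9798,48.3778
463,21.3616,32.9619,43.8659,48.2525
464,20.7282,31.0988,43.7525,48.1277
465,20.1376,29.2718,43.6396,48.0035
466,19.5852,27.5019,43.5272,47.8799
467,19.0667,25.8106,43.4154,47.7569
468,18.5777,24.2189,43.3041,47.6345
469,18.114,22.7481,43.1933,47.5127
470,17.671,21.4194,43.0831,47.3914
471,17.2453,20.2479,42.9733,47.2707
472,16.8365,19.2239,42.8641,47.1505
473,16.4453,18.3319,42.7554,47.0309
474,16.0722,17.5559,42.6471,46.9119
475,15.7177,16.8804,42.5394,46.7934
476,15.3824,16.2895,42.4322,46.6754
477,15.0668,15.7676,42.3255,46.558
478,14.7715,15.2989,42.2193,46.4412
479,14.497,14.8676,42.1135,46.3249
480,14.2439,14.4581,42.0082,46.2091
481,14.0123,14.0577,41.9035,46.0938
482,13.8002,13.6665,41.7992,45.9791
483,13.6054,13.2876,41.6953,45.8649
484,13.4256,12.9242,41.592,45.7512
485,13.2584,12.5794,41.4891,45.638
486,13.1015,12.2564,41.3867,45.5253
487,12.9526,11.9583,41.2847,45.4132
488,12.8093,11.6883,41.1832,45.3015
489,12.6693,11.4496,41.0822,45.1904
490,12.5303,11.2452,40.9816,45.0797
491,12.3906,11.0775,40.8814,44.9696
492,12.2505,10.9457,40.7818,44.8599
493,12.1112,10.8481,40.6825,44.7508
494,11.9737,10.7829,40.5837,44.6421
495,11.839,10.7484,40.4853,44.5339
496,11.7083,10.7429,40.3874,44.4261
497,11.5825,10.7648,40.2899,44.3189
498,11.4626,10.8123,40.1928,44.2121
499,11.3499,10.8838,40.0962,44.1058
500,11.2452,10.9774,40,44
501,11.1496,11.0915,39.9042,43.8946
502,11.0638,11.2232,39.8088,43.7897
503,10.9886,11.37,39.7139,43.6853
504,10.9247,11.5289,39.6194,43.5813
505,10.8727,11.6973,39.5252,43.4777
506,10.8333,11.8724,39.4315,43.3747
507,10.8074,12.0514,39.3382,43.272
508,10.7955,12.2315,39.2453,43.1698
509,10.7984,12.4099,39.1528,43.0681
510,10.8168,12.5839,39.0607,42.9667
511,10.8525,12.7517,38.969,42.8659
512,10.9118,12.9155,38.8777,42.7654
513,11.002,13.0783,38.7867,42.6654
514,11.1305,13.2434,38.6962,42.5658
515,11.3047,13.414,38.606,42.4667
516,11.532,13.5931,38.5163,42.3679
517,11.8198,13.7839,38.4269,42.2696
518,12.1753,13.9896,38.3379,42.1717
519,12.6061,14.2132,38.2493,42.0742
520,13.1194,14.4581,38.161,41.9771
521,13.7191,14.7267,38.0731,41.8805
522,14.3949,15.0194,37.9856,41.7842
523,15.1331,15.3361,37.8985,41.6883
524,15.9197,15.6765,37.8117,41.5929
525,16.741,16.0404,37.7253,41.4978
526,17.5832,16.4277,37.6393,41.4032
527,18.4323,16.8382,37.5536,41.3089
528,19.2747,17.2716,37.4682,41.2151
529,20.0965,17.7277,37.3833,41.1216
530,20.8839,18.2065,37.2986,41.0285
531,21.6295,18.7072,37.2144,40.9358
532,22.3521,19.2278,37.1304,40.8435
533,23.0766,19.7658,37.0469,40.7515
534,23.8283,20.3187,36.9636,40.66
535,24.6323,20.8839,36.8807,40.5688
536,25.4991,21.457,36.7982,40.478
537,26.3807,22.0257,36.716,40.3876
538,27.2144,22.5755,36.6341,40.2975
539,27.9376,23.0922,36.5525,40.2078
540,28.4878,23.5613,36.4713,40.1185
541,28.8011,23.9767,36.3904,40.0295
542,28.8091,24.3646,36.3099,39.9409
543,28.4711,24.7536,36.2297,39.8526
544,27.8613,25.1503,36.1498,39.7647
545,27.0829,25.5558,36.0702,39.6772
546,26.2388,25.971,35.9909,39.59
547,25.4126,26.3943,35.912,39.5032
548,24.6106,26.8131,35.8333,39.4167
549,23.8194,27.2126,35.755,39.3305
550,23.0259,27.5775,35.677,39.2447
551,22.2223,27.8947,35.5994,39.1593
552,21.4244,28.1586,35.522,39.0742
553,20.6535,28.3657,35.4449,38.9894
554,19.9307,28.5123,35.3681,38.905
555,19.2775,28.5949,35.2917,38.8209
556,18.714,28.6113,35.2155,38.7371
557,18.2565,28.5657,35.1397,38.6536
558,17.92,28.4636,35.0641,38.5705
559,17.7198,28.3109,34.9889,38.4877
560,17.671,28.113,34.9139,38.4053
561,17.7832,27.8745,34.8392,38.3232
562,18.0443,27.5956,34.7649,38.2413
563,18.4368,27.2753,34.6908,38.1598
564,18.9429,26.9126,34.617,38.0787
565,19.5452,26.5065,34.5435,37.9978
566,20.2317,26.0585,34.4702,37.9173
567,21.0134,25.5799,34.3973,37.837
568,21.9071,25.0843,34.3246,37.7571
569,22.9293,24.5854,34.2523,37.6775
570,24.0968,24.0968,34.1802,37.5982
571,25.4007,23.6318,34.1083,37.5192
572,26.7298,23.2018,34.0368,37.4405
573,27.9472,22.8176,33.9655,37.3621
574,28.9162,22.4904,33.8945,37.284
575,29.5196,22.219,33.8238,37.2062
576,29.7194,21.9549,33.7534,37.1287
577,29.5077,21.6509,33.6832,37.0515
578,28.9175,21.3134,33.6133,36.9746
579,27.9919,20.962,33.5436,36.898
580,26.7742,20.6162,33.4742,36.8216
581,25.3072,20.2893,33.4051,36.7456
582,23.6314,19.9695,33.3362,36.6698
583,21.7866,19.6383,33.2676,36.5944
584,19.8129,19.2775,33.1993,36.5192
585,17.7559,18.8723,33.1312,36.4443
586,15.6828,18.4226,33.0634,36.3697
587,13.6668,17.9318,32.9958,36.2953
588,11.7807,17.4033,32.9284,36.2213
589,10.0844,16.8407,32.8614,36.1475
590,8.5856,16.2485,32.7945,36.074
591,7.2786,15.6312,32.728,36.0008
592,6.1581,14.9936,32.6616,35.9278
593,5.2151,14.3399,32.5956,35.8551
594,4.4271,13.6737,32.5297,35.7827
595,3.7683,12.998,32.4641,35.7105
596,3.2129,12.3162,32.3988,35.6386
597,2.7382,11.632,32.3337,35.567
598,2.3344,10.9525,32.2688,35.4957
599,1.9951,10.2855,32.2041,35.4246
600,1.7136,9.6387,32.1398,35.3537
601,1.4835,9.0189,32.0756,35.2831
602,1.2992,8.4277,32.0117,35.2128
603,1.155,7.8661,31.948,35.1428
604,1.0454,7.3346,31.8845,35.073
605,0.9649,6.834,31.8213,35.0034
606,0.9079,6.365,31.7583,34.9341
607,0.8688,5.9284,31.6955,34.865
608,0.842,5.5247,31.633,34.7962
609,0.822,5.1548,31.5706,34.7277
610,0.8032,4.8194,31.5085,34.6594
611,0.7812,4.5185,31.4467,34.5913
612,0.7557,4.2501,31.385,34.5235
613,0.7277,4.0114,31.3236,34.4559
614,0.698,3.7997,31.2624,34.3886
615,0.6675,3.6124,31.2014,34.3215
616,0.6372,3.4466,31.1406,34.2547
617,0.608,3.2997,31.0801,34.1881
618,0.5807,3.169,31.0197,34.1217
619,0.5562,3.0517,30.9596,34.0556
620,0.5355,2.9452,30.8997,33.9896
621,0.5191,2.847,30.84,33.924
622,0.5068,2.7565,30.7805,33.8585
623,0.498,2.673,30.7212,33.7933
624,0.4919,2.5962,30.6621,33.7284
625,0.4881,2.5255,30.6033,33.6636
626,0.486,2.4606,30.5446,33.5991
627,0.4849,2.401,30.4862,33.5348
628,0.4843,2.3461,30.4279,33.4707
629,0.4835,2.2956,30.3699,33.4069
630,0.4819,2.249,30.3121,33.3433
631,0.4792,2.2059,30.2544,33.2799
632,0.4753,2.1659,30.197,33.2167
633,0.4705,2.1288,30.1397,33.1537
634,0.465,2.0944,30.0827,33.091
635,0.4589,2.0623,30.0259,33.0285
636,0.4526,2.0323,29.9692,32.9661
637,0.4462,2.0041,29.9128,32.9041
638,0.4399,1.9774,29.8565,32.8422
639,0.4339,1.9521,29.8005,32.7805
640,0.4284,1.9277,29.7446,32.7191
641,0.4236,1.9042,29.6889,32.6578
642,0.4195,1.8813,29.6334,32.5968
643,0.416,1.859,29.5781,32.536
644,0.413,1.8373,29.523,32.4753
645,0.4104,1.816,29.4681,32.4149
646,0.4082,1.795,29.4134,32.3547
647,0.4063,1.7744,29.3588,32.2947
648,0.4046,1.754,29.3045,32.2349
649,0.4031,1.7337,29.2503,32.1753
650,0.4016,1.7136,29.1963,32.1159
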