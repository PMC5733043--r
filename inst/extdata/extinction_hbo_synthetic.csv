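# kind: extinction
# units: mm^-1.uM^-1 (natural log)
# provenance: synthetic fixture (see data-raw/spectra_synthetic.R)
wavelength_nm,value
450,0.0144602
452,0.013533
454,0.0126687
456,0.0118661
458,0.0111237
460,0.0104393
462,0.00981058
464,0.00923508
466,0.00871023
468,0.00823344
470,0.0078022
472,0.00741407
474,0.00706676
476,0.0067581
478,0.00648456
480,0.00624156
482,0.00602509
484,0.00583169
486,0.00565831
488,0.00550226
490,0.00536118
492,0.00523292
494,0.00511558
496,0.00500742
498,0.00490685
500,0.0048124
502,0.00472464
504,0.00465154
506,0.00460255
508,0.00458692
510,0.00461441
512,0.00469606
514,0.00484533
516,0.00507907
518,0.0054058
520,0.00582286
522,0.00632629
524,0.0069093
526,0.00756009
528,0.00825969
530,0.00898008
532,0.00968754
534,0.0103587
536,0.0109723
538,0.0115064
540,0.011939
542,0.0122498
544,0.0124172
546,0.0124076
548,0.0121904
550,0.0117465
552,0.0110728
554,0.0101849
556,0.00912524
558,0.00809705
560,0.00736827
562,0.00707192
564,0.00713993
566,0.0075051
568,0.00812914
570,0.00898008
572,0.00998871
574,0.0109366
576,0.011494
578,0.0113172
580,0.0103963
582,0.00905394
584,0.00760224
586,0.00625706
588,0.00509287
590,0.00410411
592,0.00327713
594,0.00259502
596,0.00203961
598,0.00159512
600,0.00124639
602,0.000977103
604,0.000771719
606,0.000616621
608,0.000500525
610,0.000414465
612,0.000351163
614,0.000303923
616,0.000267933
618,0.00023992
620,0.000217599
622,0.000199329
624,0.000183898
626,0.000170391
628,0.000158192
630,0.000147135
632,0.000137148
634,0.000128163
636,0.000120113
638,0.000112934
640,0.000106566
642,0.000100956
644,9.60535e-05
646,9.1816e-05
648,8.82067e-05
650,8.51956e-05
652,8.27473e-05
654,8.07861e-05
656,7.92368e-05
658,7.80342e-05
660,7.71207e-05
662,7.64443e-05
664,7.59571e-05
666,7.56138e-05
668,7.53708e-05
670,7.51858e-05
672,7.50169e-05
674,7.48226e-05
676,7.45622e-05
678,7.41952e-05
680,7.36827e-05
682,7.30022e-05
684,7.21915e-05
686,7.13022e-05
688,7.0384e-05
690,6.94842e-05
692,6.86478e-05
694,6.79177e-05
696,6.7335e-05
698,6.69405e-05
700,6.6775e-05
702,6.68705e-05
704,6.72205e-05
706,6.78106e-05
708,6.86285e-05
710,6.96635e-05
712,7.09057e-05
714,7.23462e-05
716,7.3976e-05
718,7.57861e-05
720,7.77666e-05
722,7.99071e-05
724,8.21954e-05
726,8.46179e-05
728,8.71591e-05
730,8.98008e-05
732,9.25259e-05
734,9.53278e-05
736,9.82025e-05
738,0.000101145
740,0.00010415
742,0.000107212
744,0.000110323
746,0.000113475
748,0.00011666
750,0.000119868
752,0.000123088
754,0.00012631
756,0.00012952
758,0.000132706
760,0.000135853
762,0.000138948
764,0.000141988
766,0.000144971
768,0.000147895
770,0.00015076
772,0.000153565
774,0.000156311
776,0.000158998
778,0.000161626
780,0.000164198
782,0.000166715
784,0.000169179
786,0.000171592
788,0.000173959
790,0.000176289
792,0.000178588
794,0.000180865
796,0.00018313
798,0.000185392
800,0.000187661
802,0.000189945
804,0.000192245
806,0.000194559
808,0.000196885
810,0.000199222
812,0.000201565
814,0.000203915
816,0.000206268
818,0.000208621
820,0.000210973
822,0.000213321
824,0.000215662
826,0.000217993
828,0.000220311
830,0.000222614
832,0.000224898
834,0.00022716
836,0.000229398
838,0.000231607
840,0.000233784
842,0.000235926
844,0.00023803
846,0.000240092
848,0.000242108
850,0.000244074
852,0.000245988
854,0.000247848
856,0.000249655
858,0.000251408
860,0.000253108
862,0.000254753
864,0.000256345
866,0.000257884
868,0.000259369
870,0.000260802
872,0.000262182
874,0.00026351
876,0.000264786
878,0.000266011
880,0.000267185
882,0.00026831
884,0.000269385
886,0.000270412
888,0.00027139
890,0.000272322
892,0.000273208
894,0.000274049
896,0.000274846
898,0.000275599
900,0.00027631
902,0.00027698
904,0.000277608
906,0.000278192
908,0.000278733
910,0.00027923
912,0.00027968
914,0.000280084
916,0.000280442
918,0.000280751
920,0.000281011
922,0.000281222
924,0.000281382
926,0.000281491
928,0.000281549
930,0.000281555
932,0.000281507
934,0.000281406
936,0.000281251
938,0.000281042
940,0.000280777
942,0.000280457
944,0.000280081
946,0.000279648
948,0.000279159
950,0.000278613
952,0.00027801
954,0.000277352
956,0.000276643
958,0.000275884
960,0.000275079
962,0.00027423
964,0.00027334
966,0.000272412
968,0.000271449
970,0.000270452
972,0.000269425
974,0.000268371
976,0.000267291
978,0.000266189
980,0.000265067
982,0.000263928
984,0.000262773
986,0.000261607
988,0.00026043
990,0.000259245
992,0.000258055
994,0.000256861
996,0.000255667
998,0.000254474
1000,0.000253284
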