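# kind: extinction
# units: mm^-1.uM^-1 (natural log)
# provenance: synthetic fixture (see data-raw/spectra_synthetic.R)
wavelength_nm,value
450,0.0207233
452,0.0195038
454,0.0183558
456,0.017275
458,0.0162572
460,0.0152986
462,0.0143957
464,0.013545
466,0.0127435
468,0.0119882
470,0.0112764
472,0.0106056
474,0.00997326
476,0.00937734
478,0.00881757
480,0.00829512
482,0.00781054
484,0.00736388
486,0.00695471
488,0.00658235
490,0.00624586
492,0.00594422
494,0.00567635
496,0.00544124
498,0.00523793
500,0.00506569
502,0.00492411
504,0.00481375
506,0.00473559
508,0.00469103
510,0.00468204
512,0.00471133
514,0.00478258
516,0.00490053
518,0.00506656
520,0.00527812
522,0.00553261
524,0.00582711
526,0.00615795
528,0.00652031
530,0.00690776
532,0.00731303
534,0.0077317
536,0.00815947
538,0.00859113
540,0.00902053
542,0.0094406
544,0.00984394
546,0.0102247
548,0.0105774
550,0.0108966
552,0.0111768
554,0.0114129
556,0.0115996
558,0.0117194
560,0.0117432
562,0.0116494
564,0.0114464
566,0.0111516
568,0.0107838
570,0.0103616
572,0.00990426
574,0.0094343
576,0.00897234
578,0.00853432
580,0.00810899
582,0.00766436
584,0.00717492
586,0.00662503
588,0.0060336
590,0.00544201
592,0.00488193
594,0.00437449
596,0.00393167
598,0.00355094
600,0.00322125
602,0.0029334
604,0.00268
606,0.0024551
608,0.00225386
610,0.00207233
612,0.00190772
614,0.00175931
616,0.00162662
618,0.001509
620,0.00140572
622,0.00131599
624,0.00123908
626,0.00117432
628,0.00112082
630,0.00107675
632,0.00104034
634,0.00101009
636,0.000984735
638,0.000963173
640,0.000944413
642,0.000927559
644,0.000911782
646,0.000896312
648,0.000880431
650,0.000863469
652,0.000844965
654,0.000825078
656,0.000804112
658,0.000782353
660,0.000760069
662,0.000737512
664,0.000714906
666,0.00069246
668,0.000670354
670,0.000648753
672,0.000627797
674,0.000607608
676,0.000588292
678,0.000569938
680,0.00055262
682,0.000536362
684,0.000521022
686,0.000506435
688,0.000492449
690,0.00047893
692,0.000465756
694,0.000452815
696,0.000440009
698,0.000427251
700,0.000414465
702,0.000401633
704,0.000388924
706,0.000376534
708,0.000364637
710,0.000353379
712,0.000342892
714,0.000333287
716,0.000324665
718,0.000317116
720,0.000310725
722,0.000305577
724,0.000301759
726,0.000299369
728,0.000298518
730,0.000299336
732,0.000301914
734,0.000306086
736,0.000311632
738,0.000318329
740,0.000325947
742,0.000334238
744,0.000342928
746,0.000351711
748,0.000360253
750,0.000368185
752,0.000375114
754,0.000380626
756,0.000384301
758,0.000385729
760,0.000384532
762,0.000380494
764,0.000373909
766,0.000365215
768,0.000354863
770,0.000343294
772,0.000330924
774,0.000318134
776,0.000305263
778,0.000292608
780,0.00028042
782,0.000268909
784,0.000258249
786,0.000248579
788,0.000239896
790,0.000232081
792,0.000225025
794,0.000218633
796,0.000212819
798,0.000207507
800,0.000202627
802,0.000198124
804,0.000193966
806,0.000190131
808,0.000186598
810,0.000183348
812,0.000180363
814,0.000177628
816,0.000175128
818,0.00017285
820,0.000170782
822,0.000168911
824,0.000167228
826,0.000165724
828,0.000164388
830,0.000163213
832,0.000162192
834,0.000161317
836,0.000160582
838,0.00015998
840,0.000159506
842,0.000159155
844,0.000158921
846,0.0001588
848,0.000158787
850,0.000158878
852,0.000159069
854,0.000159352
856,0.000159719
858,0.000160162
860,0.000160674
862,0.000161248
864,0.000161874
866,0.000162546
868,0.000163256
870,0.000163995
872,0.000164755
874,0.000165529
876,0.000166306
878,0.00016708
880,0.00016784
882,0.000168578
884,0.000169285
886,0.000169952
888,0.000170569
890,0.000171127
892,0.000171616
894,0.000172027
896,0.000172349
898,0.000172575
900,0.000172694
902,0.000172699
904,0.000172592
906,0.000172377
908,0.000172059
910,0.000171641
912,0.000171127
914,0.000170524
916,0.000169835
918,0.000169065
920,0.00016822
922,0.000167303
924,0.00016632
926,0.000165275
928,0.000164175
930,0.000163022
932,0.000161823
934,0.000160582
936,0.000159303
938,0.000157991
940,0.00015665
942,0.000155286
944,0.000153901
946,0.000152501
948,0.000151088
950,0.000149668
952,0.000148243
954,0.000146815
956,0.000145385
958,0.000143954
960,0.000142523
962,0.000141092
964,0.000139664
966,0.000138238
968,0.000136815
970,0.000135397
972,0.000133984
974,0.000132577
976,0.000131177
978,0.000129784
980,0.0001284
982,0.000127024
984,0.000125657
986,0.0001243
988,0.000122954
990,0.00012162
992,0.000120296
994,0.000118985
996,0.000117687
998,0.000116401
1000,0.000115129
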