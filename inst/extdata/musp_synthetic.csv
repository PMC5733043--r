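# kind: mu_s_prime
# units: mm^-1
# provenance: synthetic fixture (see data-raw/spectra_synthetic.R)
wavelength_nm,value
450,2.47034
452,2.45831
454,2.4464
456,2.4346
458,2.42291
460,2.41133
462,2.39985
464,2.38847
466,2.3772
468,2.36602
470,2.35495
472,2.34398
474,2.3331
476,2.32232
478,2.31163
480,2.30104
482,2.29054
484,2.28013
486,2.26981
488,2.25958
490,2.24944
492,2.23938
494,2.22941
496,2.21952
498,2.20972
500,2.2
502,2.19036
504,2.1808
506,2.17132
508,2.16192
510,2.1526
512,2.14335
514,2.13418
516,2.12508
518,2.11605
520,2.1071
522,2.09823
524,2.08942
526,2.08068
528,2.07201
530,2.06341
532,2.05488
534,2.04642
536,2.03802
538,2.02969
540,2.02142
542,2.01322
544,2.00508
546,1.997
548,1.98898
550,1.98103
552,1.97313
554,1.9653
556,1.95753
558,1.94981
560,1.94215
562,1.93455
564,1.927
566,1.91952
568,1.91208
570,1.9047
572,1.89738
574,1.89011
576,1.88289
578,1.87572
580,1.86861
582,1.86155
584,1.85454
586,1.84758
588,1.84066
590,1.8338
592,1.82699
594,1.82022
596,1.81351
598,1.80683
600,1.80021
602,1.79363
604,1.7871
606,1.78061
608,1.77417
610,1.76777
612,1.76142
614,1.75511
616,1.74884
618,1.74262
620,1.73644
622,1.7303
624,1.7242
626,1.71814
628,1.71212
630,1.70614
632,1.7002
634,1.6943
636,1.68844
638,1.68262
640,1.67684
642,1.6711
644,1.66539
646,1.65972
648,1.65408
650,1.64848
652,1.64292
654,1.6374
656,1.63191
658,1.62645
660,1.62103
662,1.61564
664,1.61029
666,1.60497
668,1.59969
670,1.59444
672,1.58922
674,1.58403
676,1.57888
678,1.57375
680,1.56866
682,1.5636
684,1.55858
686,1.55358
688,1.54861
690,1.54367
692,1.53877
694,1.53389
696,1.52904
698,1.52422
700,1.51943
702,1.51467
704,1.50994
706,1.50524
708,1.50056
710,1.49591
712,1.49129
714,1.48669
716,1.48213
718,1.47759
720,1.47307
722,1.46858
724,1.46412
726,1.45969
728,1.45528
730,1.45089
732,1.44653
734,1.4422
736,1.43788
738,1.4336
740,1.42934
742,1.4251
744,1.42089
746,1.4167
748,1.41253
750,1.40839
752,1.40427
754,1.40017
756,1.3961
758,1.39205
760,1.38802
762,1.38401
764,1.38003
766,1.37606
768,1.37212
770,1.3682
772,1.3643
774,1.36043
776,1.35657
778,1.35273
780,1.34892
782,1.34512
784,1.34135
786,1.3376
788,1.33386
790,1.33015
792,1.32645
794,1.32278
796,1.31912
798,1.31549
800,1.31187
802,1.30827
804,1.30469
806,1.30113
808,1.29759
810,1.29407
812,1.29056
814,1.28707
816,1.2836
818,1.28015
820,1.27672
822,1.2733
824,1.2699
826,1.26652
828,1.26315
830,1.25981
832,1.25648
834,1.25316
836,1.24986
838,1.24658
840,1.24332
842,1.24007
844,1.23684
846,1.23362
848,1.23042
850,1.22724
852,1.22407
854,1.22092
856,1.21778
858,1.21466
860,1.21155
862,1.20846
864,1.20538
866,1.20232
868,1.19927
870,1.19624
872,1.19322
874,1.19022
876,1.18723
878,1.18426
880,1.1813
882,1.17835
884,1.17542
886,1.1725
888,1.16959
890,1.1667
892,1.16383
894,1.16096
896,1.15811
898,1.15528
900,1.15245
902,1.14964
904,1.14684
906,1.14406
908,1.14129
910,1.13853
912,1.13578
914,1.13305
916,1.13033
918,1.12762
920,1.12492
922,1.12224
924,1.11957
926,1.11691
928,1.11426
930,1.11163
932,1.109
934,1.10639
936,1.10379
938,1.1012
940,1.09862
942,1.09606
944,1.0935
946,1.09096
948,1.08843
950,1.08591
952,1.0834
954,1.0809
956,1.07842
958,1.07594
960,1.07347
962,1.07102
964,1.06857
966,1.06614
968,1.06372
970,1.06131
972,1.0589
974,1.05651
976,1.05413
978,1.05176
980,1.0494
982,1.04705
984,1.04471
986,1.04238
988,1.04006
990,1.03775
992,1.03544
994,1.03315
996,1.03087
998,1.0286
1000,1.02634
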