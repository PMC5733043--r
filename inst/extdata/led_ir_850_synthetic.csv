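# kind: emission
# units: arbitrary
# provenance: synthetic fixture (see data-raw/spectra_synthetic.R)
wavelength_nm,value
805,0.011109
806,0.0135384
807,0.016426
808,0.0198411
809,0.0238599
810,0.0285655
811,0.0340475
812,0.0404015
813,0.0477287
814,0.0561348
815,0.0657285
816,0.0766206
817,0.0889216
818,0.10274
819,0.118179
820,0.135335
821,0.154295
822,0.175131
823,0.197899
824,0.222635
825,0.249352
826,0.278037
827,0.308647
828,0.341108
829,0.375311
830,0.411112
831,0.448332
832,0.486752
833,0.526122
834,0.566154
835,0.606531
836,0.646905
837,0.686908
838,0.726149
839,0.764228
840,0.800737
841,0.83527
842,0.867428
843,0.89683
844,0.923116
845,0.945959
846,0.965069
847,0.980199
848,0.991151
849,0.99778
850,1
851,0.99778
852,0.991151
853,0.980199
854,0.965069
855,0.945959
856,0.923116
857,0.89683
858,0.867428
859,0.83527
860,0.800737
861,0.764228
862,0.726149
863,0.686908
864,0.646905
865,0.606531
866,0.566154
867,0.526122
868,0.486752
869,0.448332
870,0.411112
871,0.375311
872,0.341108
873,0.308647
874,0.278037
875,0.249352
876,0.222635
877,0.197899
878,0.175131
879,0.154295
880,0.135335
881,0.118179
882,0.10274
883,0.0889216
884,0.0766206
885,0.0657285
886,0.0561348
887,0.0477287
888,0.0404015
889,0.0340475
890,0.0285655
891,0.0238599
892,0.0198411
893,0.016426
894,0.0135384
895,0.011109
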