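# kind: emission
# units: arbitrary
# provenance: synthetic fixture (see data-raw/spectra_synthetic.R)
wavelength_nm,value
581,1.34687e-07
582,2.69958e-07
583,5.32697e-07
584,1.03485e-06
585,1.97921e-06
586,3.72665e-06
587,6.90812e-06
588,1.26071e-05
589,2.26509e-05
590,4.00653e-05
591,6.97696e-05
592,0.000119613
593,0.000201885
594,0.000335463
595,0.00054878
596,0.000883826
597,0.00140136
598,0.00218749
599,0.00336169
600,0.00508607
601,0.00757568
602,0.011109
603,0.0160377
604,0.0227942
605,0.0318948
606,0.0439369
607,0.0595873
608,0.0795595
609,0.104579
610,0.135335
611,0.172422
612,0.216265
613,0.267052
614,0.324652
615,0.388558
616,0.457833
617,0.531096
618,0.606531
619,0.681941
620,0.75484
621,0.822578
622,0.882497
623,0.932102
624,0.969233
625,0.992218
626,1
627,0.992218
628,0.969233
629,0.932102
630,0.882497
631,0.822578
632,0.75484
633,0.681941
634,0.606531
635,0.531096
636,0.457833
637,0.388558
638,0.324652
639,0.267052
640,0.216265
641,0.172422
642,0.135335
643,0.104579
644,0.0795595
645,0.0595873
646,0.0439369
647,0.0318948
648,0.0227942
649,0.0160377
650,0.011109
651,0.00757568
652,0.00508607
653,0.00336169
654,0.00218749
655,0.00140136
656,0.000883826
657,0.00054878
658,0.000335463
659,0.000201885
660,0.000119613
661,6.97696e-05
662,4.00653e-05
663,2.26509e-05
664,1.26071e-05
665,6.90812e-06
666,3.72665e-06
667,1.97921e-06
668,1.03485e-06
669,5.32697e-07
670,2.69958e-07
671,1.34687e-07
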