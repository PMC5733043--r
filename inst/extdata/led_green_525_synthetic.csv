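# kind: emission
# units: arbitrary
# provenance: synthetic fixture (see data-raw/spectra_synthetic.R)
wavelength_nm,value
480,0.00250085
481,0.00325419
482,0.00420949
483,0.00541309
484,0.00691977
485,0.00879363
486,0.011109
487,0.0139512
488,0.0174172
489,0.021616
490,0.0266688
491,0.0327086
492,0.0398795
493,0.0483357
494,0.0582393
495,0.0697581
496,0.0830622
497,0.0983201
498,0.115694
499,0.135335
500,0.157377
501,0.181928
502,0.209069
503,0.238842
504,0.271245
505,0.306226
506,0.343679
507,0.383437
508,0.425271
509,0.468886
510,0.513924
511,0.559965
512,0.606531
513,0.653093
514,0.699081
515,0.743893
516,0.786907
517,0.827498
518,0.865048
519,0.898967
520,0.928705
521,0.953766
522,0.973724
523,0.988235
524,0.997046
525,1
526,0.997046
527,0.988235
528,0.973724
529,0.953766
530,0.928705
531,0.898967
532,0.865048
533,0.827498
534,0.786907
535,0.743893
536,0.699081
537,0.653093
538,0.606531
539,0.559965
540,0.513924
541,0.468886
542,0.425271
543,0.383437
544,0.343679
545,0.306226
546,0.271245
547,0.238842
548,0.209069
549,0.181928
550,0.157377
551,0.135335
552,0.115694
553,0.0983201
554,0.0830622
555,0.0697581
556,0.0582393
557,0.0483357
558,0.0398795
559,0.0327086
560,0.0266688
561,0.021616
562,0.0174172
563,0.0139512
564,0.011109
565,0.00879363
566,0.00691977
567,0.00541309
568,0.00420949
569,0.00325419
570,0.00250085
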