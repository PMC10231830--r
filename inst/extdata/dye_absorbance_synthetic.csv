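"wavelength_nm","hematoxylin","eosin"
420,0.11486772911938,0.000674419549798189
425,0.125687417152511,0.00131331069521796
430,0.135569151299826,0.00247717184380523
435,0.144210247401329,0.00452580786676672
440,0.151375426519134,0.00800916820913625
445,0.156922829308347,0.013728719779475
450,0.160825246732753,0.0227941808836123
455,0.163184423882536,0.036658041953378
460,0.164236905715,0.057103912012689
465,0.164350684112537,0.0861616055108437
470,0.164012767732225,0.125925309879116
475,0.163808613293335,0.178263979585048
480,0.164395023419255,0.244436181521917
485,0.166468554570587,0.32465246735835
490,0.170731652142782,0.417660350784273
495,0.177858646187243,0.520450121020702
500,0.188463448275107,0.628183178593334
505,0.203070363978081,0.734420541666858
510,0.222088964716451,0.831676925317338
515,0.245793530757528,0.912254076828545
520,0.27430724761632,0.969233234476344
525,0.307591145237462,0.99745223067928
530,0.345437714653146,0.994276645238889
535,0.387469192342859,0.960005441285478
540,0.433140619137619,0.897824546537164
545,0.481747899333369,0.813318365129846
550,0.532441150135723,0.71364299479372
555,0.584243597915271,0.606530659712633
560,0.636076122468069,0.499316404947309
565,0.686787273557937,0.398153222213813
570,0.735188208304993,0.307521835754342
575,0.78009156494504,0.230066298993809
580,0.820352851537478,0.166717572371823
585,0.854912544790901,0.117020263922143
590,0.882836817791533,0.0795595087182277
595,0.903354688577014,0.0523931410698256
600,0.91588943048415,0.0334201275656995
605,0.920082317035015,0.0206487180621611
610,0.915807175932295,0.0123574655822352
615,0.903174767409022,0.00716336447091922
620,0.882526636056343,0.00402212914881787
625,0.854418757254291,0.00218749111818289
630,0.819595950947435,0.00115235929472752
635,0.778958610958208,0.000588004762737889
640,0.733523749890033,0.000290619734987388
645,0.68438265338518,0.0001391299679019
650,0.632657554333502,6.45160234924622e-05
655,0.579459675792532,2.89778274286711e-05
660,0.525850765320344,1.26071051770485e-05
665,0.472809881423665,5.31271176285275e-06
670,0.421206733323563,2.16854508800387e-06
675,0.371782362352555,8.57377302933679e-07
680,0.325137432091057,3.28342297208169e-07
685,0.281727906452043,1.21795994590484e-07
690,0.241867474876334,4.37613291299846e-08
695,0.205735756544298,1.52299797447126e-08
700,0.173391095106755,5.13404264070582e-09
705,0.144786645075661,1.67637409448319e-09
710,0.119788444109739,5.30192688501603e-10
715,0.098194247576135,1.62423121181012e-10
720,0.0797520532050439,4.81962549550635e-11
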