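Fp1 -0.275777 0.956919 -0.090844
F3 -0.550293 0.740639 0.385527
F7 -0.729711 0.655748 -0.193691
FT9 -0.758668 0.360876 -0.542394
FC5 -0.895081 0.414964 0.163201
FC1 -0.398850 0.430072 0.809912
C3 -0.793793 0.018573 0.607904
T7 -0.962629 0.061186 -0.263823
TP9 -0.793983 -0.191693 -0.576927
CP5 -0.927420 -0.340523 0.154714
CP1 -0.401678 -0.412349 0.817694
Pz -0.001434 -0.753560 0.657378
P3 -0.591594 -0.710103 0.381798
P7 -0.787515 -0.564924 -0.246335
O1 -0.305115 -0.938245 -0.163095
Oz -0.005521 -0.993841 -0.110682
O2 0.297800 -0.940156 -0.165597
P4 0.602868 -0.700631 0.381662
P8 0.785641 -0.564840 -0.252438
TP10 0.786956 -0.196656 -0.584831
CP6 0.933106 -0.327038 0.149528
CP2 0.423805 -0.408704 0.808301
Cz -0.000000 -0.000000 1.000000
C4 0.802960 0.028607 0.595347
T8 0.960108 0.073103 -0.269904
FT10 0.751023 0.362355 -0.551963
FC6 0.892552 0.422662 0.157189
FC2 0.400853 0.441070 0.802978
F4 0.551438 0.749449 0.366392
F8 0.725589 0.659575 -0.196167
Fp2 0.265819 0.959674 -0.091471
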