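# Synthetic, representative molar extinction spectra of oxy- (HbO) and
# deoxyhemoglobin (HbR), base-10 convention, cm^-1 M^-1.
# Constructed as smooth curves mimicking the shape and magnitude of the
# standard compiled hemoglobin spectra (Soret band, Q bands, HbR > HbO
# above 600 nm). NOT measured data: intended for simulation and testing.
# For quantitative analysis supply a measured compilation instead.
wavelength_nm,eps_hbo,eps_hbr
400,218473.4,28014.6
405,339567.8,62635.6
410,437037.9,127182.2
415,465376.5,226995.3
420,410934,351331.9
425,303145.7,468950.1
430,190515.8,538715
435,107148.6,532563.4
440,60028.8,453860.9
445,38880,335067.3
450,30805.9,216834.8
455,27463,126504.4
460,25169.9,70821.3
465,22796.3,42430.7
470,20187,30164.1
475,17463.7,25384
480,14797.5,23337.6
485,12343.9,22028.5
490,10224,20842.9
495,8520.7,19718.2
500,7289.3,18789
505,6598.6,18268.1
510,6627.5,18403.4
515,7813.8,19440.7
520,10906,21572.2
525,16608.4,24868.7
530,24674.1,29211.9
535,33088,34252.4
540,38563.3,39418.7
545,38635.9,43994.3
550,33689.8,47254.8
555,27064,48631.1
560,23464.2,47848.5
565,26568.3,44993.9
570,35477.9,40488.3
575,42817.8,34973.5
580,40673.2,29154.4
585,29659.5,23649.1
590,17518.6,18887.3
595,9739.4,15077.2
600,6197.5,12231.4
605,4708,10228.6
610,3868.4,8883.3
615,3213.3,8002.2
620,2647.8,7419.7
625,2158.6,7011.8
630,1742.3,6695.7
635,1395.4,6421.6
640,1113,6162.5
645,889.2,5906.1
650,716.8,5648
655,588.3,5388
660,495.6,5128
665,431.2,4870.3
670,388,4617.6
675,360.2,4372.4
680,342.9,4136.7
685,332.6,3912.6
690,326.7,3701.4
695,323.4,3504.3
700,321.7,3322.3
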