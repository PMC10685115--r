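# Hunt-Pointer-Estevez 2-degree cone fundamentals (energy units),
# derived from the CIE 1931 2-degree colour-matching functions,
# each class normalised to unit peak; 400-720 nm at 10 nm steps
# columns: wavelength_nm L M S
400 0.000529 0.000314 0.038316
410 0.001528 0.000973 0.117036
420 0.004535 0.003533 0.364314
430 0.01005 0.011861 0.781897
440 0.014765 0.026207 0.985892
450 0.018584 0.046324 1
460 0.024398 0.075715 0.941933
470 0.039251 0.113645 0.726596
480 0.072208 0.167167 0.458778
490 0.124613 0.241479 0.262513
500 0.212312 0.365149 0.15349
510 0.353142 0.55686 0.089273
520 0.530853 0.769087 0.044128
530 0.684962 0.912573 0.023814
540 0.803937 0.985979 0.011455
550 0.892699 1 0.004909
560 0.958741 0.965459 0.002201
570 0.996206 0.88247 0.001185
580 1 0.759595 0.000959
590 0.963467 0.61211 0.000621
600 0.887348 0.466164 0.000451
610 0.77089 0.338367 0.000169
620 0.622619 0.236055 0.000113
630 0.45268 0.153921 0
640 0.308586 0.096601 0
650 0.192607 0.05701 0
660 0.11114 0.031802 0
670 0.058668 0.016492 0
680 0.031317 0.008683 0
690 0.015157 0.004161 0
700 0.007599 0.00207 0
710 0.003876 0.001069 0
720 0.001902 0.000479 0
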