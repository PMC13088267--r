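wavelength_nm,n,k
340,2.14571,0
360,2.12889,0
380,2.11465,0
400,2.1025,0
420,2.09204,0
440,2.08298,0
460,2.07507,0
480,2.06813,0
500,2.062,0
520,2.05657,0
540,2.05173,0
560,2.0474,0
580,2.04351,0
600,2.04,0
620,2.03683,0
640,2.03395,0
660,2.03132,0
680,2.02893,0
700,2.02673,0
720,2.02472,0
740,2.02287,0
760,2.02116,0
780,2.01959,0
800,2.01812,0
820,2.01677,0
840,2.01551,0
860,2.01434,0
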