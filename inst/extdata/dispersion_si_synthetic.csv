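wavelength_nm,n,k
340,5.3,2.99
360,6,2.9
370,6.87,2
380,6.55,1
400,5.57,0.387
420,5,0.245
450,4.67,0.148
480,4.42,0.08
500,4.29,0.045
520,4.19,0.033
550,4.08,0.028
580,3.99,0.022
600,3.94,0.02
620,3.9,0.017
650,3.85,0.014
680,3.81,0.012
700,3.78,0.01
730,3.75,0.008
760,3.72,0.007
800,3.69,0.006
830,3.67,0.005
860,3.65,0.004
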