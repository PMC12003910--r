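"label","x","y"
"Fp1",-0.31,0.95
"Fp2",0.31,0.95
"F7",-0.81,0.59
"F3",-0.45,0.55
"Fz",0,0.52
"F4",0.45,0.55
"F8",0.81,0.59
"FC1",-0.22,0.27
"FC2",0.22,0.27
"T7",-1,0
"C3",-0.52,0
"Cz",0,0
"C4",0.52,0
"T8",1,0
"CP1",-0.22,-0.27
"CP2",0.22,-0.27
"P7",-0.81,-0.59
"P3",-0.45,-0.55
"Pz",0,-0.52
"P4",0.45,-0.55
"P8",0.81,-0.59
"POz",0,-0.78
"O1",-0.31,-0.95
"O2",0.31,-0.95
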