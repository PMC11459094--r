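index,se_bp,r_bp,se_ev,r_ev
RA,76.02092616,0.615,9.64037899,0.754
ABC,70.83996637,0.678,9.06843885,0.786
M1,82.10335013,0.524,10.5989982,0.692
M2,86.03267444,0.451,11.34996569,0.634
SCI,86.40526283,0.443,11.40039383,0.63
F,69.49911131,0.693,9.0606885,0.787
GA,72.63612711,0.657,9.30315409,0.774
H,86.75378512,0.436,11.45839242,0.625
HM,75.03459712,0.628,9.62001605,0.755
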