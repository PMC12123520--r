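sample_id,reference_alleles,hsww_detected,hsww_dropin,hswa_detected,hswa_dropin
M1,42,34,6,15,0
M2,44,43,1,2,0
M3,41,41,36,6,0
M4,43,13,2,0,0
M5,45,45,0,9,0
M6,43,34,6,1,0
F1,38,35,4,2,0
F2,36,13,1,0,0
F3,45,40,0,1,0
F4,40,17,0,0,0
F5,45,11,0,4,0
F6,42,18,2,0,0
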