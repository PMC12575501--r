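patient,artery,size_class,protrusion_mm
1,RRA,nominal,4.27
1,LRA,nominal,4.01
2,RRA,nominal,3.90
2,LRA,nominal,4.01
1,RRA,shorter,3.51
1,LRA,shorter,4.02
2,RRA,shorter,3.68
2,LRA,shorter,3.63
1,RRA,longer,4.27
1,LRA,longer,4.00
2,RRA,longer,4.01
2,LRA,longer,4.12
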