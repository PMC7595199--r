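model,class,tn,fn,tp,fp
severity,control,8,3,6,8
severity,small,19,4,0,2
severity,moderate,13,6,3,3
severity,large,20,3,0,2
moderate_large_vs_rest,moderate_large,12,4,7,2
stroke_vs_control,stroke,3,4,12,6
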