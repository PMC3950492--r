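linkage,carbons,unsat
acyl,16,0
acyl,16,1
acyl,18,0
acyl,18,1
acyl,18,2
acyl,18,3
acyl,20,4
acyl,22,6
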