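"tip","range"
"t9","C"
"t2","BC"
"t5","BD"
"t8","AC"
"t11","A"
"t7","A"
"t12","A"
"t6","A"
"t4","AB"
"t3","D"
"t10","C"
"t1","A"
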