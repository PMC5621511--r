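((((t9:0.0086,t2:0.0086):2.7477,t5:2.7563):6.1746,(t8:8.753,(t11:8.3532,((t7:1.0651,t12:1.0651):0.2284,t6:1.2935):7.0597):0.3998):0.1778):11.0691,((t4:0.3543,t3:0.3543):2.9896,(t10:0.8006,t1:0.8006):2.5433):16.6561);
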