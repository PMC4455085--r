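sample_id,rvsb,rvsg
REF,0.4,0.4
CF1,0,0
CF2,0,0
CF3,0.484,0
CF4,0,0
CF5,0,0
CF6,0.444,0.54
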