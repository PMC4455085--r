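sample_id,weight_mg,diameter_mm,thickness_mm
CF1,306,9.2,3.4
CF2,241,9.2,3.2
CF3,343,9.2,3.7
CF4,304,10,3.7
CF5,260,9.3,3.5
CF6,243,9.2,3.2
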