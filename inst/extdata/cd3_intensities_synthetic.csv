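sample_id,group,intensity
AUTH1,authentic,148.2
AUTH2,authentic,151.7
AUTH3,authentic,149.5
AUTH4,authentic,153.1
AUTH5,authentic,147.8
AUTH6,authentic,150.4
AUTH7,authentic,152.2
AUTH8,authentic,146.9
AUTH9,authentic,149.9
AUTH10,authentic,151.2
AUTH11,authentic,148.8
AUTH12,authentic,150.6
CF1,counterfeit,191.4
CF2,counterfeit,187.9
CF3,counterfeit,112.3
CF4,counterfeit,195.2
CF5,counterfeit,189.6
CF6,counterfeit,171.8
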