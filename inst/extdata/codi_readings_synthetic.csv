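sample_id,group,intensity_open,intensity_filtered
AUTH1,authentic,2,1.212121212121212
AUTH2,authentic,2,1.159420289855073
AUTH3,authentic,2,1.111111111111111
AUTH4,authentic,2,1.075268817204301
AUTH5,authentic,2,1.041666666666667
AUTH6,authentic,2,1.036269430051813
AUTH7,authentic,2,1.025641025641026
AUTH8,authentic,2,0.987654320987654
AUTH9,authentic,2,0.952380952380952
AUTH10,authentic,2,0.892857142857143
AUTH11,authentic,2,0.833333333333333
AUTH12,authentic,2,0.761904761904762
CF1,counterfeit,2,1.526717557251908
CF2,counterfeit,2,1.568627450980392
CF3,counterfeit,2,0.655737704918033
CF4,counterfeit,2,1.612903225806452
CF5,counterfeit,2,1.476014760147601
CF6,counterfeit,2,1.739130434782609
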