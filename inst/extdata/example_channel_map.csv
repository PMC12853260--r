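channel,roi,hemisphere,seed
ch1,A,ipsilesional,TRUE
ch2,A,ipsilesional,FALSE
ch3,B,ipsilesional,FALSE
ch4,B,ipsilesional,FALSE
ch5,C,contralesional,FALSE
ch6,C,contralesional,FALSE
ch7,S,medial,FALSE
ch8,unassigned,NA,FALSE
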