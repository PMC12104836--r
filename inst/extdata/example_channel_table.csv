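name,x,y,z,electrode_type,hemisphere,roi_id,roi_name
LHIPP1,-29.83,-15.10,-9.69,depth,left,17,Left-Hippocampus
LHIPP2,-34.91,-15.10,-8.60,depth,left,17,Left-Hippocampus
LHIPP3,-39.70,-15.10,-7.65,depth,left,17,Left-Hippocampus
LHIPP4,-44.59,-14.44,-6.77,depth,left,39,lh-middle-temporal
LHIPP5,-49.29,-14.44,-5.68,depth,left,39,lh-middle-temporal
LHIPP6,-54.36,-13.71,-4.86,depth,left,39,lh-middle-temporal
LHIPP7,-58.97,-13.71,-4.29,depth,left,39,lh-middle-temporal
LHIPP8,-64.14,-13.24,-3.15,depth,left,39,lh-middle-temporal
LHIPP9,-68.00,-13.24,-2.46,depth,left,39,lh-middle-temporal
LHIPP10,-73.33,-13.24,-1.29,depth,left,39,lh-middle-temporal
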