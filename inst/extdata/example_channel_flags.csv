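name,is_resected,is_spiking,is_structurally_abnormal,is_within_soz
LHIPP1,0,1,0,1
LHIPP2,0,1,0,1
LHIPP3,0,1,0,0
LHIPP4,0,1,0,0
LHIPP5,0,1,0,0
LHIPP6,0,0,0,0
LHIPP7,0,0,0,0
LHIPP8,0,0,0,0
LHIPP9,0,0,0,0
LHIPP10,0,0,0,0
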