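id,age,group,panss_total,panss_positive,panss_negative,panss_general
H001,23.4,healthy,,,,
H002,31.0,healthy,,,,
H003,47.2,healthy,,,,
H004,19.8,healthy,,,,
P01,27,psychosis,37,9,8,20
P02,24,psychosis,59,11,18,30
P03,30,psychosis,49,14,13,22
P04,21,psychosis,41,9,9,23
P05,33,psychosis,56,16,11,29
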