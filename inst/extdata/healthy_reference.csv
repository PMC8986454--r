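"event","mean_ms","sd_ms","n"
"MC",4,11,41
"AO",-3,11,39
"AC",-5,12,39
"MO",-7,19,39
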