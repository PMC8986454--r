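"event","center","halfwidth"
"MC",4,22
"AO",-3,22
"AC",-5,23
"MO",-7,37
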