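"patient_id","diagnosis","ef_band","waveform_class"
"P001","HF",">50%","NT"
"P002","HF","40-50%","NT"
"P003","HF","40-50%","NT"
"P004","HF","40-50%","NT"
"P005","HF","<40%","NT"
"P006","HF","<40%","NT"
"P007","HF","<40%","NT"
"P008","HF","<40%","NT"
"P009","HF","<40%","NT"
"P010","HF","<40%","NT"
"P011","HF","<40%","NT"
"P012","HF","<40%","NT"
"P013","HF","<40%","NT"
"P014","HF","<40%","NT"
"P015","HF","<40%","NT"
"P016","HF","<40%","NT"
"P017","HF","<40%","NT"
"P018","HF","<40%","NT"
"P019","HF","<40%","NT"
"P020","HF","<40%","NT"
"P021","HF","<40%","NT"
"P022","HF",,"NT"
"P023","HF",">50%","T"
"P024","HF",">50%","T"
"P025","HF","40-50%","T"
"P026","HF","40-50%","T"
"P027","HF","40-50%","T"
"P028","HF","40-50%","T"
"P029","HF","<40%","T"
"P030","HF","<40%","T"
"P031","HF","<40%","T"
"P032","HF","<40%","T"
"P033","HF","<40%","T"
"P034","HF","<40%","T"
"P035","HF","<40%","T"
"P036","HF","<40%","T"
"P037","HF","<40%","T"
"P038","HF","<40%","T"
"P039","HF","<40%","T"
"P040","HF","<40%","T"
"P041","HF","<40%","T"
"P042","HF","<40%","T"
"P043","HF","<40%","T"
"P044","HF","<40%","T"
"P045","HF","<40%","T"
"P046","HF","<40%","T"
"P047","HF","<40%","T"
"P048","HF",,"T"
"P049","HF",,"T"
"P050","MI",">50%","NT"
"P051","MI",">50%","NT"
"P052","MI","40-50%","NT"
"P053","MI","40-50%","NT"
"P054","MI","40-50%","NT"
"P055","MI","<40%","NT"
"P056","MI","<40%","NT"
"P057","MI","<40%","NT"
"P058","MI",">50%","T"
"P059","MI",">50%","T"
"P060","MI",">50%","T"
"P061","MI",">50%","T"
"P062","MI","40-50%","T"
"P063","MI","40-50%","T"
"P064","MI","40-50%","T"
"P065","MI","40-50%","T"
"P066","MI","40-50%","T"
"P067","MI","40-50%","T"
"P068","MI","40-50%","T"
"P069","MI","40-50%","T"
"P070","MI","40-50%","T"
"P071","MI","<40%","T"
"P072","MI","<40%","T"
"P073","MI","<40%","T"
"P074","MI","<40%","T"
"P075","MI","<40%","T"
"P076","MI","<40%","T"
"P077","MI","<40%","T"
"P078","MI","<40%","T"
"P079","MI","<40%","T"
"P080","MI","<40%","T"
"P081","MI","<40%","T"
"P082","MI","<40%","T"
"P083","MI",,"T"
"P084","TX",">50%","NT"
"P085","TX",">50%","NT"
"P086","TX","40-50%","NT"
"P087","TX","<40%","NT"
"P088","TX",">50%","T"
"P089","TX",">50%","T"
"P090","TX","40-50%","T"
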