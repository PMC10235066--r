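record_type,count
polygon,240713
point,22091
printed_total,262804
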