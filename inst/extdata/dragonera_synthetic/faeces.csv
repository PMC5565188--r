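microhabitat,count
OPEN,114
EPHEDRA,9
PISTACIA,17
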