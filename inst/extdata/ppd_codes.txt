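# Synthetic postpartum-depression diagnosis code set (one code per line).
# Real deployments supply their own depression code list here; codes are
# opaque tokens matched exactly against diagnosis events.
DX:PPD
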