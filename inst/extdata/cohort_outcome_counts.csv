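outcome,events,total,printed_rate
survival,1665,2629,63.3
intervention,604,2629,23.0
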