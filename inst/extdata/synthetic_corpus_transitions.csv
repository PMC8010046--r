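context,outcome,probability
<start>,definite_noun,0.55
<start>,indefinite_noun,0.45
definite_noun,definite_adjective,0.35
definite_noun,indefinite_adjective,0.65
indefinite_noun,indefinite_adjective,0.9
indefinite_noun,definite_adjective,0.1
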