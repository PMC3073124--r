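variant	canonical
Dermatobranchus_tongshanensis	Dermatobranchus_tongashanensis
Dermatobranchus_gonatophora	Dermatobranchus_gonatophorus
Heterodoris_robustus	Heterodoris_robusta
Histiomena_marginatum	Histiomena_marginata
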