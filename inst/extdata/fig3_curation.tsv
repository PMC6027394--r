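source	source_type	target	target_type	edge_type	provenance
H_plus_sensor	sensor	rcfB	regulon	uncertain	literature
H_plus_sensor	sensor	tm_unknown	transmembrane_protein	uncertain	literature
rcfB	regulon	llrA	regulon	uncertain	literature
rcfB	regulon	llrC	regulon	uncertain	literature
rcfB	regulon	hllA	regulon	uncertain	literature
rcfB	regulon	NHP6A	regulon	uncertain	literature
rcfB	regulon	ccpA	regulon	uncertain	literature
rcfB	regulon	Regulon8	regulon	uncertain	literature
rcfB	regulon	Regulon39	regulon	uncertain	literature
rcfB	regulon	Acid response	functional_module	regulates	literature
tm_F0F1ATPase	transmembrane_protein	F0/F1ATPase	functional_module	maps_to	literature
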