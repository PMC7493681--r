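product_id	label
A1	B. longum
A2	B. bifidum
A2	B. longum
A3	B. animalis subsp. lactis
B4	Bifidus
B4	Lactic acid bacteria
B6	Lactic acid bacteria
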