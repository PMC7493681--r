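product_id	taxon	ct
A1	B. longum subsp. longum	14.2
A2	B. bifidum	13.1
A2	B. longum subsp. longum	15.0
A3	B. animalis subsp. lactis	12.4
B4	B. animalis subsp. lactis	15.8
B6	B. animalis subsp. lactis	14.9
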