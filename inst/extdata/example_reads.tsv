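4
1
5
11807.4	12200.9	5921.3	6105.8
12410.0	5788.2	6056.1	-312.7
11590.6	11988.4	6214.9	403.2
12096.2	12304.5	5730.0	5998.6
5873.1	6122.8	255.4	-140.9
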