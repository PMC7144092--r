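label	segment	genes	scored	wings_percent	thorax_percent
Df(3R)Exel6164	87B5-87B10	GstD1-D11	72	95.8	62.5
Df(2R)BSC335	55C6-55F1	GstE1-E11	59	91.5	86.4
Df(2R)BSC856	60E1-60E4	GstE12	68	77.9	83.8
Df(2R)BSC271	44F12-45A12	GstE13	67	94.0	77.6
Df(2R)BSC273	49F4-50A13	GstE14	66	92.4	90.9
Df(3L)BSC157	66C12-66D6	GstO1-O4	150	94.7	70.0
Df(2R)BSC132	45F6-46B4	GstT1-T2	51	68.6	9.80
Df(1)Exel6254	19C4-19D1	GstT3	34	91.2	94.2
Df(1)Exel6245	11E11-11F4	GstT4	26	23.1	80.8
Df(3R)by10	85D8-85E13	GstZ1-Z2	57	89.5	91.2
Df(2R)BSC433	53F4-53F8	GstS1	56	12.5	35.7
No deficiency	NA	NA	44	88.6	90.9
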