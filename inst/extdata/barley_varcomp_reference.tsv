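trait	habit	dataset	sigma2_G	sigma2_Y	sigma2_e	E	h2
FT	spring	historical	24.9	48.1	24.82	4.42	0.82
FT	spring	enhanced	27.62	48.7	16.08	4.37	0.88
FT	winter	historical	10.57	73.72	15.32	3.49	0.71
FT	winter	enhanced	12.83	71.32	9.13	3.4	0.83
PH	spring	historical	133.24	116.39	95.76	4.26	0.86
PH	spring	enhanced	134.97	116.5	91.57	4.25	0.86
PH	winter	historical	156.75	232.4	90.53	3.49	0.86
PH	winter	enhanced	161.52	233.7	84.71	3.47	0.87
TGW	spring	historical	44.23	17.85	18.13	4.45	0.92
TGW	spring	enhanced	45.19	17.73	16.38	4.43	0.92
TGW	winter	historical	37.79	17.51	14.01	3.4	0.9
TGW	winter	enhanced	39.68	17.27	10.97	3.38	0.92
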