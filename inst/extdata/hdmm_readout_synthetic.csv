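applied_x_mm,applied_y_mm,applied_z_mm,readout_x_mm,readout_y_mm,readout_z_mm
0.25,0,0,0.285,-0.023,0.0386
0.5,0,0,0.5015,-0.0047,-7e-04
0.75,0,0,0.774,-0.0825,-2e-04
1,0,0,1.0159,0,0.0313
1.25,0,0,1.266,0.0036,0.0383
1.45,0,0,1.4595,-0.0034,0.0234
0.25,0,0,0.2703,0.0094,-0.0102
0.5,0,0,0.5029,-0.0127,-0.0103
0.75,0,0,0.8164,-0.0497,0.0802
1,0,0,1.0012,2e-04,0.0136
1.25,0,0,1.2768,-0.018,0.0178
1.45,0,0,1.5101,0.0451,0.0148
0,0.25,0,0.016,0.2507,-0.0075
0,0.5,0,0.0104,0.511,0.0309
0,0.75,0,-0.0134,0.7524,0.002
0,1,0,0.0025,0.9934,0.0065
0,1.25,0,0.0105,1.2968,0.0515
0,1.45,0,-0.0292,1.4673,0.0465
0,0.25,0,-0.0309,0.2513,0.07
0,0.5,0,0,0.5,0.001
0,0.75,0,0.0102,0.7623,0.0327
0,1,0,-0.0157,1.0012,0.0678
0,1.25,0,0.0137,1.1435,-0.0219
0,1.45,0,-0.0047,1.4578,-0.01
0,0,0.25,0.0311,-0.0076,0.2315
0,0,0.5,0.0022,0.0012,0.4861
0,0,0.75,0.003,0.0017,0.7518
0,0,1,-0.013,0.0395,1.0402
0,0,1.25,0.0225,-0.0229,1.31
0,0,1.45,0.0045,0.0373,1.5044
0,0,0.25,-0.0012,1e-04,0.2484
0,0,0.5,0.0323,0.0327,0.591
0,0,0.75,0.0092,0.01,0.7458
0,0,1,1e-04,1e-04,1.0022
0,0,1.25,0.0116,-0.0162,1.2513
0,0,1.45,0.0086,3e-04,1.4512
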