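# iconqa hdmm log v1
# session_id: iroc_phantom_synthetic
# threshold_mm: 1.5
# record_trigger_mm: 0.2
# window_ms: 500
t_s,x_mm,y_mm,z_mm,radial_mm,state,event
0,-0.09,0.06,0.06,0.09,treating,baseline
310.5,-0.05,0.03,0.08,0.12,treating,record
642,-0.07,0.01,0.09,0.33,treating,record
1180.5,-0.04,0.02,0.1,0.21,treating,record
1555,-0.08,0,0.11,0.3,treating,record
1903.5,-0.06,0.02,0.09,0.22,treating,end
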