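t,furrow_width_um,spindle_length_um
0.0,13.0,30.0
0.1,12.0,34.8
0.2,10.9,38.5
0.3,9.9,41.8
0.4,8.8,44.4
0.5,7.8,46.6
0.6,6.7,48.2
0.7,5.7,49.3
0.8,4.6,50.4
0.9,3.6,51.8
1.0,NA,53.6
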