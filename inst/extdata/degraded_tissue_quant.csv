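sample_id,kit_label,c_small,c_large,x_small,x_large
D1,QT,119.710,83.6300,80,214
D2,QT,0.058,0.0009,80,214
D3,QT,45.605,1.5170,80,214
D4,QT,0.437,0.1357,80,214
D5,QT,0.256,0.0111,80,214
D6,QT,0.098,0.0079,80,214
D7,QT,0.284,0.0036,80,214
D8,QT,1.437,0.0900,80,214
D9,QT,31.510,0.0565,80,214
D1,PQ,127.850,27.7100,84,294
D2,PQ,0.003,NA,84,294
D3,PQ,59.950,1.8600,84,294
D4,PQ,0.547,0.0540,84,294
D5,PQ,0.333,0.0042,84,294
D6,PQ,0.119,0.0024,84,294
D7,PQ,0.292,0.0034,84,294
D8,PQ,1.712,0.0859,84,294
D9,PQ,55.710,0.0077,84,294
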