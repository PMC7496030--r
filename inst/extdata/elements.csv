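element,nominal_shift,mass,abundance
C,0,12.0,0.9893
C,1,13.00335484,0.0107
H,0,1.00782503,0.999885
H,1,2.01410178,0.000115
N,0,14.00307401,0.99636
N,1,15.00010890,0.00364
O,0,15.99491462,0.99757
O,1,16.99913176,0.00038
O,2,17.99915961,0.00205
S,0,31.97207069,0.9499
S,1,32.97145876,0.0075
S,2,33.96786690,0.0425
S,4,35.96708076,0.0001
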