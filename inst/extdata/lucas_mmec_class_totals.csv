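class,count
B11,47143
B12,8062
B13,31500
B14,7296
B15,6582
B16,32175
B21,4113
B22,4414
B31,6830
B32,13958
B33,1603
B55,5784
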