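band,population
18-19,1290000
20-24,3680000
25-29,3870000
30-34,3720000
35-39,3550000
40-44,3490000
45-49,3860000
50-54,3830000
55-59,3380000
60-64,2900000
65-69,2910000
70-74,2300000
75-79,1790000
80-84,1400000
85-89,900000
90-94,430000
95+,120000
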