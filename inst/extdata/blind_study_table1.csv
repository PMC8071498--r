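sample_number,presumptive_sex,actual_sex
1,female,female
2,male,male
3,female,female
4,female,female
5,female,female
6,female,female
7,female,female
8,male,male
9,female,female
10,female,female
11,male,male
12,female,female
13,male,female
14,male,male
15,female,female
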