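value,label
-1.661,1
0.945,1
0.495,1
0.473,1
1.498,1
1.011,1
0.682,1
1.943,1
-0.543,1
0.188,1
0.835,1
2.976,1
1.465,1
2.056,1
3.178,1
0.619,1
2.09,1
0.551,1
2.296,1
2.373,1
0.637,1
1.196,1
-0.049,1
0.169,1
0.809,1
0.735,1
1.844,1
1.446,1
1.093,1
-0.531,1
-0.417,0
-0.763,0
-0.9,0
-0.65,0
-0.396,0
-0.737,0
0.827,0
-0.406,0
0.614,0
0.065,0
-1.46,0
1.018,0
-0.824,0
0.755,0
-0.539,0
-0.819,0
0.399,0
-0.384,0
-0.203,0
1.148,0
0.658,0
0.7,0
-0.632,0
1.569,0
-0.72,0
2.378,0
-0.49,0
-1.16,0
1.779,0
-0.152,0
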