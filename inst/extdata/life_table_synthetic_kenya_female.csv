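"age","q_annual"
30,0.0045982082
31,0.0046557778
32,0.0047188127
33,0.0047878313
34,0.0048634011
35,0.0049461436
36,0.0050367387
37,0.0051359308
38,0.0052445349
39,0.0053634427
40,0.0054936305
41,0.0056361666
42,0.0057922201
43,0.0059630707
44,0.0061501184
45,0.0063548953
46,0.0065790775
47,0.0068244991
48,0.0070931662
49,0.0073872733
50,0.0077092206
51,0.0080616332
52,0.0084473814
53,0.0088696036
54,0.0093317307
55,0.0098375127
56,0.010391048
57,0.010996814
58,0.011659702
59,0.012385056
60,0.013178707
61,0.014047024
62,0.014996954
63,0.016036078
64,0.017172661
65,0.018415715
66,0.019775054
67,0.021261372
68,0.022886306
69,0.024662514
70,0.026603758
71,0.028724989
72,0.031042435
73,0.033573697
74,0.036337844
75,0.039355518
76,0.042649034
77,0.046242483
78,0.05016184
79,0.054435065
80,0.059092198
81,0.064165454
82,0.069689298
83,0.075700516
84,0.082238257
85,0.089344055
86,0.097061814
87,0.10543776
88,0.11452032
89,0.12435999
90,0.13500905
91,0.14652129
92,0.15895152
93,0.17235507
94,0.18678707
95,0.20230161
96,0.21895074
97,0.23678322
98,0.25584314
99,0.27616822
100,1
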