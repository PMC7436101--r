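no,lambda
1,3
2,5
3,3
4,4
5,4
6,0
7,4
8,4
9,4
10,2
11,1
12,2
13,0
14,3
15,3
16,3
17,3
18,3
19,2
20,2
21,0
22,0
23,0
24,0
25,0
26,0
27,1
28,0
29,0
30,3
31,4
32,4
33,3
34,4
35,3
36,1
37,0
38,3
39,4
40,3
41,4
42,4
43,1
44,1
45,1
46,0
47,5
48,3
49,2
50,3
51,4
52,3
53,0
54,2
55,2
56,4
57,1
58,1
59,1
60,4
61,4
62,2
63,4
64,5
65,4
66,5
67,2
68,3
69,3
70,3
71,2
72,0
73,0
74,0
75,2
76,4
77,5
78,4
79,2
80,0
81,0
82,0
83,3
84,4
85,0
86,3
87,0
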