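participant,core,receptive,expressive,content,structure
1,45,45,45,45,45
2,45,45,45,45,45
3,45,45,45,45,45
4,45,45,56,45,59
5,50,53,50,57,55
6,53,59,53,53,50
7,53,59,57,59,57
8,65,63,65,67,71
9,69,63,75,69,81
10,77,67,69,71,79
11,65,63,77,75,88
12,69,71,75,79,83
13,73,69,81,75,86
14,73,73,83,77,91
15,79,69,81,79,90
16,81,75,87,79,90
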