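no,true,predicted
1,32.5,25.65
2,34,40.1
3,65,60.5
4,73,79.25
5,85,80.25
6,93,87.62
7,118,110.4
8,125,132.2
9,146,154.2
10,150,142.65
11,180,186.3
12,186,180.6
13,210,200.4
14,213,219.0
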