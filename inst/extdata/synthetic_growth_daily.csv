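day,well,rfu
0,A1,40.4
1,A1,39.2
2,A1,49.2
3,A1,120
4,A1,318.7
5,A1,547.5
6,A1,736.1
7,A1,813.6
8,A1,867.3
9,A1,870.9
10,A1,877.4
11,A1,873.8
12,A1,883.5
13,A1,883.7
14,A1,843.8
0,A2,56.5
1,A2,55.8
2,A2,67.8
3,A2,162.6
4,A2,450.2
5,A2,786.5
6,A2,1023.7
7,A2,1110.4
8,A2,1225.3
9,A2,1210.1
10,A2,1263.6
11,A2,1262.1
12,A2,1221.6
13,A2,1236.5
14,A2,1263.7
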