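-1 0 0 1 -1 -2 0 1 1 0 0 0 -2 1 1 1 2 1 10 0
2 1 2 -1 -1 2 -1 1 -2 -1 -2 1 -1 -3 1 0 3 8 5 1
1 -1 -3 1 2 2 0 2 0 2 1 1 12 -3 -1 5 3 2 3 3
2 -1 0 0 1 -3 0 1 0 1 14 1 -1 0 1 0 -1 -3 3 0
0 0 -2 -2 1 0 2 -2 -2 0 -1 0 -1 0 -4 2 4 0 9 3
13 4 -1 1 1 3 -2 3 -2 1 -2 1 -3 1 -1 -1 2 3 0 1
-2 -3 0 -1 12 -1 -1 -3 2 3 2 0 0 -1 3 -1 4 -2 2 -1
0 10 1 1 -1 1 -2 -2 1 -5 0 0 4 -3 1 3 -1 -3 1 -1
0 1 1 -2 2 -1 3 2 0 15 -3 1 -2 0 0 -3 -1 0 1 -1
3 1 1 -1 -1 3 -1 1 12 2 -4 -2 3 2 4 1 2 0 0 2
-5 -1 3 1 3 0 -1 0 2 -1 2 -3 11 0 3 4 -3 -1 -1 4
0 5 -3 -1 0 2 1 -2 0 4 1 2 2 2 -4 11 4 0 -1 1
0 0 -1 -1 0 2 1 0 -3 -1 -4 0 2 0 -1 2 3 -1 0 14
0 11 -3 3 -2 3 0 0 0 4 2 2 0 0 -1 -1 -3 -1 0 -2
1 7 0 1 0 -3 0 0 0 1 0 0 1 0 -1 0 -1 -4 -1 0
1 2 2 2 -3 1 3 -1 1 5 0 3 0 0 0 -2 -1 0 10 -1
2 2 0 2 4 -2 2 0 -1 10 -1 0 0 0 -1 0 2 -2 -1 -2
4 0 -2 0 2 0 -1 -2 1 -2 8 -3 -1 -3 2 1 2 2 1 0
0 -1 1 -2 4 -1 0 -1 -2 10 -1 -3 1 -1 3 -1 -1 0 0 2
2 0 -3 -1 1 -5 1 0 -1 0 11 1 2 2 0 -1 -4 1 1 2
-1 0 -2 1 -1 1 -2 0 0 1 11 -1 3 -1 -2 0 2 -4 1 0
3 1 1 3 1 -2 11 5 1 -1 1 0 -5 1 -4 -2 -3 0 1 -3
4 0 2 -1 -1 0 3 1 -2 -1 1 1 -1 12 0 1 0 1 2 3
-2 1 0 2 1 13 0 0 -1 -2 1 -4 4 0 -2 0 3 -3 -2 2
-3 0 1 0 -2 3 1 2 3 -1 -1 -2 2 -3 0 11 -2 4 3 0
0 -4 1 2 -2 3 -1 3 3 0 -1 3 1 8 1 1 2 0 -1 -1
-1 2 2 -2 -5 -1 -3 -2 0 0 0 4 -3 -1 -2 -4 0 15 0 0
-3 2 3 -2 12 1 0 2 -1 1 -1 -2 -1 -4 -2 4 1 0 0 -1
15 0 0 3 3 -5 2 1 -1 0 -3 -2 3 0 -1 -1 0 0 0 -1
3 -5 -5 -2 2 -1 1 1 1 9 -3 0 3 0 1 -1 -4 1 1 3
-5 -3 -1 2 -1 3 -3 -1 -2 -5 2 1 8 -1 -1 0 -3 -3 1 -1
-1 1 1 0 1 0 2 0 2 0 -3 0 -2 -5 -5 -2 -2 3 -1 10
-1 -1 -1 -1 1 -3 2 0 -1 2 2 1 -1 3 3 2 0 12 -4 0
-1 2 0 -2 13 0 2 -2 0 0 -1 -2 -1 2 -1 1 2 0 3 1
0 5 -1 -3 1 -3 3 1 14 1 -1 2 -2 0 0 1 -2 3 -2 -1
-1 0 -2 -2 11 0 -1 -1 1 -2 0 2 1 -1 2 -1 2 -1 -3 -2
0 -1 -2 0 0 1 0 -3 2 4 1 3 -1 -2 -2 -3 0 2 -2 11
0 -3 0 -2 1 -3 1 -3 1 11 0 -1 1 -2 -1 2 2 0 0 -1
11 0 -2 -2 3 0 3 1 5 2 1 2 -1 -2 2 -1 -2 -1 2 4
2 -1 -2 3 3 0 3 1 -2 0 1 2 0 0 2 -3 -1 0 13 2
0 -3 -1 1 14 -3 -1 1 1 1 1 3 0 3 -1 0 3 2 0 1
-1 -1 -3 -1 13 -2 -1 0 2 1 1 0 -1 2 0 2 -1 -3 -1 -1
-1 1 10 2 1 -3 -2 1 4 -3 4 -1 3 -2 -4 0 4 -2 3 -2
-1 2 1 -3 12 1 2 3 -1 4 -2 4 -1 1 -1 3 1 1 0 2
2 -2 0 0 -1 0 2 3 -1 0 0 -1 12 -1 1 0 2 1 -3 -1
11 1 -2 -1 4 -2 -2 2 1 -2 3 -2 2 -2 -1 2 3 3 2 0
-2 1 -1 -1 1 15 1 1 -1 0 -2 0 -1 0 -1 1 0 0 1 2
1 0 9 2 2 0 -1 1 3 -3 0 -2 -1 1 -1 2 2 -3 0 -3
1 -2 11 -1 0 5 0 -3 1 2 -2 -1 1 0 1 -1 -5 1 1 -3
1 -1 9 -1 -2 0 2 -1 4 0 -4 -2 -3 4 2 -2 3 0 0 0
8 0 -5 1 0 -1 2 1 2 -1 0 -1 -2 0 1 -1 0 -2 1 3
2 0 -2 1 2 1 9 -1 -3 -1 3 1 0 -2 0 -1 3 -2 0 -3
5 -2 0 2 -1 1 2 5 0 1 2 0 1 -2 1 1 0 1 -2 14
1 3 2 -3 0 -2 -1 -1 -2 0 2 9 -3 2 -1 1 -2 0 -1 2
-5 11 -4 -1 2 -4 -1 -3 2 0 0 -5 -5 2 -1 1 1 -3 0 1
7 2 0 -2 0 3 1 1 -2 -2 1 1 -1 0 1 2 0 2 1 -2
0 2 0 0 -1 3 12 0 -2 0 1 -2 1 2 0 1 -2 2 0 -3
-2 3 3 -2 -1 0 10 0 1 -1 -2 -1 -2 -2 -1 0 -1 3 -1 3
3 -2 3 2 -1 -1 1 0 10 1 2 1 -1 -2 1 0 -2 1 2 1
-2 3 0 3 1 0 -2 0 1 5 5 -2 -2 -2 0 4 -3 -1 1 11
1 -4 0 2 0 12 4 0 1 1 -1 3 -2 2 -2 -3 0 0 1 -3
0 0 0 -1 3 -2 0 -4 -2 2 1 1 5 -3 1 -1 0 3 -4 9
-2 2 1 -1 0 5 1 5 2 2 3 -2 12 -2 3 -2 -2 -1 2 -3
0 1 -1 -1 2 2 1 3 0 1 -3 -3 0 1 -1 11 0 4 -1 0
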