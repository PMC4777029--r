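! Queen-contiguity neighbour lists for the 18 governorates of Iraq,
! region ids in the order of the published 2007 survey analysis.
! Reconstructed from public governorate geography and calibrated against
! the published per-governorate local Moran values (see iraq2007_notes.md).
18
1 2
2 5
2 4
1 5 7 12
3 4
4 5 6 12
4 3
3 5 12
5 5
1 2 3 4 12
6 4
3 8 11 12
7 6
2 8 9 10 12 13
8 6
6 7 9 10 11 12
9 6
7 8 10 11 13 14
10 4
7 8 9 13
11 6
6 8 9 14 16 17
12 7
2 3 4 5 6 7 8
13 5
7 9 10 14 15
14 5
9 11 13 15 16
15 4
13 14 16 18
16 5
11 14 15 17 18
17 3
11 16 18
18 3
15 16 17
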