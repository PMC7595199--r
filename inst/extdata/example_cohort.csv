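id,group,severity,lateralization,days_post_onset,nihss,gender,age
1,control,control,none,,,M,91
2,stroke,small,left,6,0,M,87
3,stroke,moderate,left,7,8,F,61
4,stroke,moderate,left,1,12,M,65
5,stroke,moderate,left,3,16,F,83
6,stroke,small,right,3,0,F,19
7,stroke,moderate,right,2,1,F,71
8,stroke,moderate,left,4,14,M,71
9,stroke,small,left,1,8,F,86
10,stroke,moderate,left,0,10,M,85
11,stroke,moderate,left,8,15,M,37
12,stroke,large,right,16,10,M,87
13,control,control,none,,,M,66
14,stroke,large,left,2,14,F,53
15,control,control,none,,,M,53
16,stroke,small,left,3,1,M,66
17,control,control,none,,,F,64
18,control,control,none,,,F,81
19,stroke,moderate,left,2,2,M,75
20,control,control,none,,,M,56
21,stroke,moderate,left,0,10,M,87
22,control,control,none,,,M,59
23,control,control,none,,,F,48
24,stroke,large,right,6,10,F,72
25,control,control,none,,,M,29
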