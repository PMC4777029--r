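id,name_guess,ur_transformed,ci_transformed
1,Duhok,10.02,11.41
2,Nineveh,15.80,12.43
3,Sulaymaniyah,2.14,24.02
4,Kirkuk,6.55,-4.13
5,Erbil,5.12,14.66
6,Diyala,18.31,2.35
7,Anbar,9.30,7.46
8,Baghdad,12.04,8.97
9,Babil,8.51,8.97
10,Kerbala,13.05,3.92
11,Wasit,10.71,6.39
12,Salahuddin,7.62,0.24
13,Najaf,11.38,19.65
14,Qadisiyah,14.13,17.54
15,Muthanna,14.91,13.50
16,Thiqar,21.28,10.43
17,Missan,16.87,15.97
18,Basrah,13.05,5.23
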