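"site_id","x_nm","y_nm","z_nm","role","logical_bit"
1,-35,25,0,"marker_filled",
2,-25,25,0,"marker_filled",
3,-15,25,0,"marker_empty",
4,-5,25,0,"marker_empty",
5,5,25,0,"marker_empty",
6,15,25,0,"marker_empty",
7,25,25,0,"marker_filled",
8,35,25,0,"marker_filled",
9,-35,15,0,"marker_filled",
10,-25,15,0,"char_bit",1
11,-15,15,0,"char_bit",2
12,-5,15,0,"char_bit",3
13,5,15,0,"char_bit",4
14,15,15,0,"char_bit",5
15,25,15,0,"char_bit",6
16,35,15,0,"marker_filled",
17,-35,5,0,"marker_empty",
18,-25,5,0,"char_bit",1
19,-15,5,0,"char_bit",2
20,-5,5,0,"char_bit",3
21,5,5,0,"char_bit",4
22,15,5,0,"char_bit",5
23,25,5,0,"char_bit",6
24,35,5,0,"marker_empty",
25,-35,-5,0,"marker_empty",
26,-25,-5,0,"pos_bit",7
27,-15,-5,0,"pos_bit",8
28,-5,-5,0,"pos_bit",9
29,5,-5,0,"pos_bit",10
30,15,-5,0,"pos_bit",11
31,25,-5,0,"pos_bit",12
32,35,-5,0,"marker_empty",
33,-35,-15,0,"marker_filled",
34,-25,-15,0,"pos_bit",7
35,-15,-15,0,"pos_bit",8
36,-5,-15,0,"pos_bit",9
37,5,-15,0,"pos_bit",10
38,15,-15,0,"pos_bit",11
39,25,-15,0,"pos_bit",12
40,35,-15,0,"marker_empty",
41,-35,-25,0,"marker_filled",
42,-25,-25,0,"marker_filled",
43,-15,-25,0,"marker_empty",
44,-5,-25,0,"marker_empty",
45,5,-25,0,"marker_empty",
46,15,-25,0,"marker_filled",
47,25,-25,0,"marker_filled",
48,35,-25,0,"marker_filled",
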