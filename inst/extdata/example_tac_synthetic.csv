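"frame_index","t_start_min","t_end_min","value","units"
1,0,1,0.431369086390829,"SUV"
2,1,2,1.18416440909697,"SUV"
3,2,3,1.5298449063632,"SUV"
4,3,4,1.67754426788963,"SUV"
5,4,6,1.74679075819283,"SUV"
6,6,8,1.75274902702086,"SUV"
7,8,10,1.72798904740888,"SUV"
8,10,12,1.69587560877937,"SUV"
9,12,14,1.66218689955082,"SUV"
10,14,16,1.62850777020202,"SUV"
11,16,18,1.59530184178178,"SUV"
12,18,20,1.56270506429157,"SUV"
13,20,25,1.50735158682847,"SUV"
14,25,30,1.43145235410503,"SUV"
15,30,35,1.35937227553935,"SUV"
16,35,40,1.29092158931023,"SUV"
17,40,45,1.22591770145643,"SUV"
18,45,50,1.16418706009826,"SUV"
19,50,55,1.10556484276015,"SUV"
20,55,60,1.04989452592001,"SUV"
21,60,65,0.997027467701175,"SUV"
22,65,70,0.946822511032263,"SUV"
23,70,75,0.899145606754865,"SUV"
24,75,80,0.853869455707338,"SUV"
25,80,85,0.810873168831174,"SUV"
26,85,90,0.770041944392577,"SUV"
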