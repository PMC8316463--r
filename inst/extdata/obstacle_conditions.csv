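condition,label,obstacle_width,obstacle_lateral_offset,am_left,am_right
1,NOBST,0,0,NA,NA
2,C2,45,0,83.5,83.5
3,C3,90,0,61.0,61.0
4,C4,90,22,84.0,40.0
5,C5,90,-22,40.0,84.0
6,C6,135,0,39.0,39.0
7,C7,135,13.5,52.0,25.0
8,C8,135,-13.5,25.0,52.0
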