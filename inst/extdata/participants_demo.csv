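"participant_id","age","gender","dep_1","dep_2","dep_3","dep_4","dep_5","dep_6","dep_7","dep_8","anx_1","anx_2","anx_3","anx_4","anx_5","anx_6"
"P01",26,"f",1,2,3,4,0,1,2,3,2,3,4,0,1,2
"P02",27,"m",2,4,1,3,0,2,4,1,4,1,3,0,2,4
"P03",28,"f",3,1,4,2,0,3,1,4,1,4,2,0,3,1
"P04",29,"m",4,3,2,1,0,4,3,2,3,2,1,0,4,3
"P05",30,"f",0,0,0,0,0,0,0,0,0,0,0,0,0,0
"P06",31,"m",1,2,3,4,0,1,2,3,2,3,4,0,1,2
"P07",32,"f",2,4,1,3,0,2,4,1,4,1,3,0,2,4
"P08",33,"m",3,1,4,2,0,3,1,4,1,4,2,0,3,1
"P09",34,"f",4,3,2,1,0,4,3,2,3,2,1,0,4,3
"P10",35,"m",0,0,0,0,0,0,0,0,0,0,0,0,0,0
"P11",36,"f",1,2,3,4,0,1,2,3,2,3,4,0,1,2
"P12",37,"m",2,4,1,3,0,2,4,1,4,1,3,0,2,4
"P13",38,"f",3,1,4,2,0,3,1,4,1,4,2,0,3,1
"P14",39,"m",4,3,2,1,0,4,3,2,3,2,1,0,4,3
"P15",40,"f",0,0,0,0,0,0,0,0,0,0,0,0,0,0
"P17",42,"f",,,,,,,,,4,1,3,0,2,4
"P18",43,"m",3,1,4,2,0,3,1,4,1,4,2,0,3,1
"P19",44,"f",4,3,2,1,0,4,3,2,3,2,1,0,4,3
"P20",45,"m",0,0,0,0,0,0,0,0,0,0,0,0,0,0
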