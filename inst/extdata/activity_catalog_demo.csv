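code,name,category,met_none,met_light,met_medium,met_hard,met_sitting,met_standing
SLP1,Sleeping,1,0.95,,,,,
REC1,Lying quietly awake,1,1.3,,,,,
PC1,Showering and toweling off,2,2.0,,,,,
PC2,Grooming and dressing,2,2.5,,,,,
EAT1,Eating a meal,3,,,,,1.5,2.0
CK1,Cooking or food preparation,3,,,,,1.8,2.5
WLK1,Walking for transportation,4,,2.8,3.5,4.3,,
CYC1,Bicycling,4,,3.5,6.8,10.0,,
DRV1,Driving a car,4,2.5,,,,,
BUS1,Riding in a bus or train,4,1.3,,,,,
HH1,Washing dishes,5,1.8,,,,,
HH2,Cleaning or vacuuming,5,3.3,,,,,
LND1,Doing laundry,5,2.0,,,,,
DSK1,Office or computer work,6,,,,,1.3,1.8
OCC2,Light manual work standing,6,3.0,,,,,
OCC3,Heavy manual labour,6,,4.0,5.5,7.0,,
SHP1,Grocery shopping,7,2.3,,,,,
ERR1,Errands and appointments,7,2.0,,,,,
TV1,Watching television,8,1.3,,,,,
RDG1,Reading,8,,,,,1.3,1.8
MUS1,Playing a musical instrument,8,2.5,,,,,
GME1,Board or card games,8,1.5,,,,,
RUN1,Running,9,,6.0,8.3,11.0,,
SWM1,Swimming,9,,4.8,7.0,9.8,,
SOC1,Playing soccer,9,7.0,,,,,
GYM1,Strength training,9,,3.5,5.0,6.0,,
VIS1,Conversing or socializing,10,,,,,1.5,1.8
CHD1,Active play with children,10,3.5,,,,,
HIK1,Hiking,11,,5.3,6.5,7.8,,
FSH1,Fishing,11,,,,,2.0,3.5
GRD1,Gardening,12,3.8,,,,,
MOW1,Mowing the lawn,12,5.0,,,,,
WAI1,Waiting or idling,13,,,,,1.3,1.8
MED1,Meditating or relaxing,13,1.0,,,,,
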