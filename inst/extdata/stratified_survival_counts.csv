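age_bin,severity,endotype,alive,expired,printed_rate
young,mild,HE,193,5,97.5
young,mild,AA,5,1,83.3
young,mild,HTN,6,1,85.7
young,moderate,HE,84,5,94.4
young,moderate,AA,4,1,80.0
young,moderate,HTN,2,0,100.0
young,severe,HE,237,56,80.9
young,severe,AA,11,3,78.6
young,severe,HTN,18,4,81.8
middle-aged,mild,HE,177,11,94.1
middle-aged,mild,AA,35,15,70.0
middle-aged,mild,HTN,109,16,87.2
middle-aged,moderate,HE,73,12,85.9
middle-aged,moderate,AA,21,7,75.0
middle-aged,moderate,HTN,28,7,80.0
middle-aged,severe,HE,140,70,66.7
middle-aged,severe,AA,33,16,67.3
middle-aged,severe,HTN,40,36,52.6
old,mild,HE,38,30,55.9
old,mild,AA,10,5,66.7
old,mild,HTN,158,153,50.8
old,moderate,HE,11,15,42.3
old,moderate,AA,1,1,50.0
old,moderate,HTN,39,71,35.5
old,severe,HE,19,56,25.3
old,severe,AA,3,3,50.0
old,severe,HTN,41,130,24.0
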