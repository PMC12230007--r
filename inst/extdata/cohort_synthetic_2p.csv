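participant_id,timepoint,age,sex,education,hgs,bmi,weight_loss_3mo,appetite_loss,wears_glasses,vision_difficulty,uses_hearing_aid,hearing_difficulty,tug,chair_stand,sit_reach,balance,gds15,moca
P01,0,62,F,high,30,24.5,0,0,0,0,0,0,9,14,2,25,0,28
P01,1,62,F,high,31,24.0,0,0,0,0,0,0,8.5,15,2.5,30,0,29
P02,0,66,M,low,25,21.0,3,1,1,1,0,0,12,11,-5,15,12,20
P02,1,66,M,low,28,23.0,0,0,1,1,0,0,9.5,12,0,22,8,22
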