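column,type,codes,units,description
participant_id,character,,,Opaque participant identifier; unique per person
timepoint,integer,0=baseline; 1=follow-up,,Assessment occasion
age,numeric,,years,Age at baseline (>= 60)
sex,character,F; M,,Sex
education,character,config-defined bands,,Education band label matched against the MoCA cutoff table
hgs,numeric,,kgf,Maximal handgrip strength (dynamometer)
bmi,numeric,,kg/m2,Body mass index
weight_loss_3mo,numeric,,kg,Unintentional weight loss over the last 3 months (0 = none)
appetite_loss,logical,0=no; 1=yes,,Self-reported appetite loss
wears_glasses,logical,0=no; 1=yes,,Wears prescription glasses
vision_difficulty,logical,0=no; 1=yes,,Difficulty seeing far or near
uses_hearing_aid,logical,0=no; 1=yes,,Uses a hearing aid
hearing_difficulty,logical,0=no; 1=yes,,Difficulty hearing whispers
tug,numeric,,seconds,Timed Up and Go completion time
chair_stand,integer,,repetitions,Sit-to-stand repetitions in the test interval
sit_reach,numeric,,cm,Sit-and-reach distance (negative = short of the feet)
balance,numeric,,seconds,One-leg stand hold time
gds15,integer,,points,Geriatric Depression Scale (15-item) total (0-15)
moca,integer,,points,Montreal Cognitive Assessment total (0-30)
sensory,numeric,,points,Scored output: sensory domain (0/1/2)
psychological,numeric,,points,Scored output: psychological domain (0/1/2)
cognitive,numeric,,points,Scored output: cognition domain (0/2)
vitality,numeric,,points,Scored output: vitality domain (0-2 by 0.5)
locomotion,numeric,,points,Scored output: locomotion domain (0-2 by 0.5)
composite,numeric,,points,Scored output: composite intrinsic capacity (0-10 by 0.5)
category,character,low; moderate; high,,Scored output: composite classification
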