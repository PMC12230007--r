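# Example threshold configuration.
#
# The `fixed` block repeats the package defaults for documentation purposes.
# The `norms` and `moca` blocks are SYNTHETIC ILLUSTRATIVE STAND-INS in the
# style of senior fitness test reference tables and education-adjusted MoCA
# screening cutoffs: plausible magnitudes with full coverage (ages 60-99,
# both sexes), NOT values from any published norm edition. Substitute your
# population's norms before drawing conclusions from real data.
fixed:
  hgs_male_min: 27.0
  hgs_female_min: 16.0
  bmi_low: 22.0
  bmi_high: 27.0
  tug_max: 10.0
  balance_min: 20.0
  weight_loss_kg: 3.0
  gds_band_edges: [5, 10]
  composite_low_max: 4.0
  composite_moderate_max: 8.0
norms:
  - {sex: F, age_min: 60, age_max: 64, chair_stand_min: 12, sit_reach_min: -0.5, sit_reach_max: 5.0}
  - {sex: F, age_min: 65, age_max: 69, chair_stand_min: 11, sit_reach_min: -0.5, sit_reach_max: 4.5}
  - {sex: F, age_min: 70, age_max: 74, chair_stand_min: 10, sit_reach_min: -1.0, sit_reach_max: 4.0}
  - {sex: F, age_min: 75, age_max: 79, chair_stand_min: 10, sit_reach_min: -1.5, sit_reach_max: 3.5}
  - {sex: F, age_min: 80, age_max: 84, chair_stand_min: 9, sit_reach_min: -2.0, sit_reach_max: 3.0}
  - {sex: F, age_min: 85, age_max: 89, chair_stand_min: 8, sit_reach_min: -2.5, sit_reach_max: 2.5}
  - {sex: F, age_min: 90, age_max: 99, chair_stand_min: 4, sit_reach_min: -4.5, sit_reach_max: 1.0}
  - {sex: M, age_min: 60, age_max: 64, chair_stand_min: 14, sit_reach_min: -2.5, sit_reach_max: 4.0}
  - {sex: M, age_min: 65, age_max: 69, chair_stand_min: 12, sit_reach_min: -3.0, sit_reach_max: 3.0}
  - {sex: M, age_min: 70, age_max: 74, chair_stand_min: 12, sit_reach_min: -3.5, sit_reach_max: 2.5}
  - {sex: M, age_min: 75, age_max: 79, chair_stand_min: 11, sit_reach_min: -4.0, sit_reach_max: 2.0}
  - {sex: M, age_min: 80, age_max: 84, chair_stand_min: 10, sit_reach_min: -5.5, sit_reach_max: 1.5}
  - {sex: M, age_min: 85, age_max: 89, chair_stand_min: 8, sit_reach_min: -6.0, sit_reach_max: 0.5}
  - {sex: M, age_min: 90, age_max: 99, chair_stand_min: 7, sit_reach_min: -6.5, sit_reach_max: -0.5}
moca:
  - {education: low, cutoff: 21}
  - {education: medium, cutoff: 24}
  - {education: high, cutoff: 26}
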