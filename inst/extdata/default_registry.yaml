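# clinenrich packaged feature registry (23 oncology clinical features).
# classes: closed vocabulary (the reserved "not_present" class is injected
#   automatically). severity: least -> most clinically severe; "@numeric"
#   expands to the ascending numeric class family of bounded_numeric
#   features; omitted severity defaults to the listed class order.
version: 1
features:
- feature_id: figo
  display_name: FIGO stage
  question: What is the FIGO stage?
  aliases: [figo stage, figo]
  value_kind: ordinal
  classes: ["1", "1a", "1b", "1c", "2", "2a", "2b", "3", "3a", "3b", "3c", "4", "4a", "4b"]
- feature_id: grade
  display_name: Grade
  question: What is the tumour grade?
  aliases: [grade]
  value_kind: ordinal
  classes: ["1", "2", "3", "4"]
- feature_id: p53
  display_name: P53
  question: What is the p53 status?
  aliases: [p53]
  value_kind: categorical
  classes: [positive, negative]
  severity: [negative, positive]
- feature_id: mmr
  display_name: MMR
  question: What is the MMR status?
  aliases: [mmr status, mmr, mismatch repair]
  value_kind: categorical
  classes: [intact, deficient]
  severity: [intact, deficient]
- feature_id: mlh1
  display_name: MLH1
  question: What is the MLH1 status?
  aliases: [mlh1]
  value_kind: categorical
  classes: [present, absent]
  severity: [present, absent]
- feature_id: msh2
  display_name: MSH2
  question: What is the MSH2 status?
  aliases: [msh2]
  value_kind: categorical
  classes: [present, absent]
  severity: [present, absent]
- feature_id: msh6
  display_name: MSH6
  question: What is the MSH6 status?
  aliases: [msh6]
  value_kind: categorical
  classes: [present, absent]
  severity: [present, absent]
- feature_id: pms2
  display_name: PMS2
  question: What is the PMS2 status?
  aliases: [pms2]
  value_kind: categorical
  classes: [present, absent]
  severity: [present, absent]
- feature_id: myometrial_invasion
  display_name: Myometrial Invasion
  question: Is myometrial invasion present?
  aliases: [myometrial invasion]
  value_kind: categorical
  classes: [present, absent]
  severity: [absent, present]
- feature_id: lymphovascular_invasion
  display_name: Lymphovascular Invasion
  question: Is lymphovascular invasion present?
  aliases: [lymphovascular invasion, lvi]
  value_kind: categorical
  classes: [present, absent]
  severity: [absent, present]
- feature_id: her2
  display_name: Her2
  question: What is the HER2 status?
  aliases: [her2, her-2, her2/neu]
  value_kind: categorical
  classes: [positive, equivocal, negative, "1", "2", "3"]
  severity: [negative, "1", equivocal, "2", positive, "3"]
- feature_id: er
  display_name: ER
  question: What is the ER status?
  aliases: [er status, oestrogen receptor, er]
  value_kind: bounded_numeric
  numeric_range: [0, 8]
  classes: [positive, negative]
  severity: [negative, "@numeric", positive]
- feature_id: pr
  display_name: PR
  question: What is the PR status?
  aliases: [pr status, progesterone receptor, pr]
  value_kind: bounded_numeric
  numeric_range: [0, 8]
  classes: [positive, negative]
  severity: [negative, "@numeric", positive]
- feature_id: tnm_t
  display_name: TNM staging T
  question: What is the TNM T stage?
  aliases: [t stage, tnm t]
  value_kind: ordinal
  classes: ["0", "1", "1a", "1b", "1c", "2", "3", "3a", "3b", "4", "4a", "4b"]
- feature_id: tnm_n
  display_name: TNM staging N
  question: What is the TNM N stage?
  aliases: [n stage, tnm n]
  value_kind: ordinal
  classes: [x, "0", "1", "1a", "1b", "2", "2a", "2b", "2c", "3", "3a", "3b"]
- feature_id: tnm_m
  display_name: TNM staging M
  question: What is the TNM M stage?
  aliases: [m stage, tnm m]
  value_kind: ordinal
  classes: [x, "0", "1", "1a", "1b", "1c"]
- feature_id: tnm_edition
  display_name: TNM staging Edition
  question: Which TNM staging edition was used?
  aliases: [tnm edition, tnm staging edition]
  value_kind: ordinal
  classes: ["5", "7", "8"]
- feature_id: blast_cell_percentage
  display_name: Blast cell Percentage
  question: What is the blast cell percentage?
  aliases: [blast cell percentage, blast cells, blasts]
  value_kind: bounded_numeric
  numeric_range: [0, 100]
  classes: [no_excess, an_excess]
  severity: [no_excess, an_excess, "@numeric"]
- feature_id: alk
  display_name: ALK
  question: What is the ALK status?
  aliases: [alk]
  value_kind: categorical
  classes: [positive, negative, equivocal]
  severity: [negative, equivocal, positive]
- feature_id: cga
  display_name: CgA
  question: What is the chromogranin status?
  aliases: [chromogranin, cga]
  value_kind: categorical
  classes: [positive, negative]
  severity: [negative, positive]
- feature_id: egfr
  display_name: EGFR
  question: What is the EGFR status?
  aliases: [egfr]
  value_kind: categorical
  classes: [positive, negative]
  severity: [negative, positive]
- feature_id: synaptophysin
  display_name: Synaptophysin
  question: What is the synaptophysin status?
  aliases: [synaptophysin]
  value_kind: categorical
  classes: [positive, negative]
  severity: [negative, positive]
- feature_id: ttf1
  display_name: TTF1
  question: What is the TTF1 status?
  aliases: [ttf1, ttf-1]
  value_kind: categorical
  classes: [positive, negative]
  severity: [negative, positive]
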