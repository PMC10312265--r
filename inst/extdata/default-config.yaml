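version: "1.0-calibrated-2026-09"
nNeurons: 200
decayA:
  "CB+": 52.82
  "PV+": 52.82
  "CB-": 52.82
  "PV-": 52.82
  TRN_M: 149.0
  TRN_C: 149.0
  L1-3a: 39.16
  L3b-4: 39.16
  L5: 39.16
  L6: 39.16
eExt: 1.0
eInh: -1.0
gains:
  l6_pv: 5.48
  pv_trnc: 5.0
  l6_trnc: 250.0
  trnc_pv: 2.04
  trnc_trnc: 11.17
  pv_l3b4: 300.0
  l3b4_l6: 300.0
  pv_pvm: 60.0
  pvm_pv: 60.0
  trnc_pvm: 120.0
  cb_trnm: 5.0
  trnm_cb: 43.0
  trnm_trnm: 11.17
  cb_l13a: 300.0
  l13a_l5: 300.0
  cb_cbm: 60.0
  cbm_cb: 60.0
  trnm_cbm: 120.0
  mix_cortical: 4.0
  mix_thal: 20.0
  mix_cr: 4.0
sigmas:
  core: 3.0
  matrix: 12.0
centerOffsets:
  trn_tc: 0
  tc_trn: 0
  tc_cortex: 0
l5TrnFraction: 0.05
l5CbOverL6Pv: 20.0
localInhibition:
  core: false
  matrix: false
corticalFeedbackTC: false
corticalFeedbackTRN: true
mixingMode: none
mixingRatio: 0.5
mixingEfficacy: 1.0
transfer: signed
stimGain: 30.0
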