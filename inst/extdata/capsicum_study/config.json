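{
  "provenance": {
    "scenario": "Chronic adult consumer, South of Bolivar: 250 g/week (35.7 g/day) sweet pepper, 70 kg body weight, daily exposure over a 70-year lifetime",
    "rfd": "USEPA IRIS oral reference doses",
    "csf": "OEHHA oral cancer slope factors",
    "bmdl": "EFSA CONTAM lead benchmark doses (ug/kg BW/day)",
    "ptwi": "JECFA provisional tolerable weekly intake (ug/kg BW/week)",
    "mac": "GB 2762-2022 and Codex Alimentarius CXS 193-1995 (amended 2024) limits for vegetables (mg/kg)"
  },
  "scenario": {
    "fir_g_day": 35.7,
    "bw_kg": 70,
    "ef_days_yr": 365,
    "ed_years": 70,
    "at_days": 25550
  },
  "reference_values": {
    "rfd": { "Hg": 0.0003, "Pb": 0.0035, "As": 0.0003 },
    "csf": { "Pb": 0.0085, "As": 1.5 },
    "bmdl": { "Pb": { "children_iq": 0.5, "adults_ckd": 0.63, "adults_sbp": 1.50 } },
    "ptwi": { "Hg": 4 },
    "mac": {
      "Hg": { "GB 2762-2022": 0.01 },
      "Pb": { "GB 2762-2022": 0.1, "Codex CXS 193-1995": 0.05 },
      "As": { "GB 2762-2022": 0.5 }
    }
  }
}
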