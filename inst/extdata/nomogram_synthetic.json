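{
  "description": "SYNTHETIC nomogram calibration for five-year survival after radical cystectomy. Structure mirrors a published points-based nomogram (five indices -> points -> total points -> probability); the point values and the probability curve are synthetic placeholders, not a transcription of any published model.",
  "points": {
    "path_stage": {
      "pT0": 0, "pTa/pTi/pTis": 8, "pT1": 20, "pT2": 45, "pT3": 75, "pT4": 100
    },
    "lvi": { "no": 0, "yes": 35 },
    "node_stage": { "N0": 0, "N1": 40, "N2": 60, "N3": 80 },
    "neoadjuvant_chemo": { "yes": 0, "no": 15 },
    "adjuvant_radiotherapy": { "no": 0, "yes": 10 }
  },
  "probability_knots": [
    { "total_points": 0, "probability": 0.92 },
    { "total_points": 50, "probability": 0.8 },
    { "total_points": 100, "probability": 0.62 },
    { "total_points": 150, "probability": 0.42 },
    { "total_points": 200, "probability": 0.25 },
    { "total_points": 240, "probability": 0.12 }
  ],
  "horizon_years": 5
}
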