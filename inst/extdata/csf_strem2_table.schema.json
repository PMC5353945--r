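{
  "description": "CSF soluble TREM2 clinical table: one row per subject (46 sporadic ALS patients, 20 controls). Transcribed verbatim; 'Unavailable'/'NA' mark missing fields. Control age_at_sample entries are kept as transcribed but are ambiguous and excluded from computation.",
  "columns": {
    "group": {"type": "string", "values": ["ALS", "Control"]},
    "sex": {"type": "string", "values": ["M", "F"]},
    "onset_age_years": {"type": "number", "unit": "years", "missing": "controls and one ALS subject"},
    "duration_years": {"type": "number", "unit": "years", "note": "symptom onset to death", "missing": "controls and one ALS subject"},
    "age_at_sample": {"type": "string", "note": "verbatim transcription; numeric for ALS rows"},
    "percent_course": {"type": "number", "unit": "percent", "range": [0, 100], "note": "position in the onset-to-death interval at CSF sampling"},
    "strem2_ng_ml": {"type": "number", "unit": "ng/ml", "note": "soluble TREM2 concentration, > 0"}
  },
  "md5": "c3b7863678e476dfad3c479ba24bbe07"
}
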