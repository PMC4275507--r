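# Engine thresholds; see ?hc_config for units and meaning.
behavior_cutoff: 4
knowledge_tolerance: 0
importance_threshold: 7
confidence_threshold: 7
struggle_weeks: 3
followup_days: 60
met_fraction: 1.0
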