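# Example simulation parameters for the `simulate` subcommand; values per
# behavior in order physical_activity, low_salt_diet, fluid_restriction,
# medication_intake. See ?cohort_params.
n_patients: 123
horizon_days: 364
seed: 1
p_nonadherent: [0.407, 0.455, 0.049, 0.049]
p_start_coaching: [0.70, 0.839, 0.667, 0.667]
p_knowledge_gap: 0.3
p_weekly_achieve: 0.6
p_continue_after_adherent: [0.607, 0.361, 0.50, 0.75]
p_stop_later: [0.529, 0.462, 0.0, 0.333]
p_relapse_at_followup: [0.308, 0.067, 0.0, 0.0]
p_retry_after_relapse: [0.75, 0.0, 0.0, 0.0]
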