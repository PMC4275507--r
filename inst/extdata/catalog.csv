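"content_id","behavior","kind","text"
"video_physical_activity","physical_activity","video","Video: physical activity"
"video_low_salt_diet","low_salt_diet","video","Video: low salt diet"
"video_fluid_restriction","fluid_restriction","video","Video: fluid restriction"
"video_medication_intake","medication_intake","video","Video: medication intake"
"video_symptom_monitoring","symptom_monitoring","video","Video: symptom monitoring"
"video_alcohol","alcohol","video","Video: alcohol"
"video_sleep","sleep","video","Video: sleep"
"tip_physical_activity","physical_activity","tip","Tips: physical activity"
"tip_low_salt_diet","low_salt_diet","tip","Tips: low salt diet"
"tip_fluid_restriction","fluid_restriction","tip","Tips: fluid restriction"
"tip_medication_intake","medication_intake","tip","Tips: medication intake"
"tip_symptom_monitoring","symptom_monitoring","tip","Tips: symptom monitoring"
"tip_alcohol","alcohol","tip","Tips: alcohol"
"tip_sleep","sleep","tip","Tips: sleep"
"activity_not_safe","physical_activity","myth_truth","Myth: Physical activity is not safe for people with heart failure. Truth: It is important to be physically active and to rest regularly in between."
"salt_food_tasteless","low_salt_diet","myth_truth","Myth: Low-salt food has no taste. Truth: herbs and spices keep meals tasty."
"fluid_thirst_harmful","fluid_restriction","myth_truth","Myth: Restricting fluids is harmful. Truth: an agreed limit reduces congestion."
"medication_only_when_ill","medication_intake","myth_truth","Myth: Medication is only needed when feeling unwell. Truth: daily intake keeps you stable."
"barrier_physical_activity","physical_activity","barrier_tip","Practical tips for everyday barriers: physical activity"
"barrier_low_salt_diet","low_salt_diet","barrier_tip","Practical tips for everyday barriers: low salt diet"
"barrier_fluid_restriction","fluid_restriction","barrier_tip","Practical tips for everyday barriers: fluid restriction"
"barrier_medication_intake","medication_intake","barrier_tip","Practical tips for everyday barriers: medication intake"
"ready_physical_activity","physical_activity","encouragement","You seem ready to work on physical activity - let's set a goal."
"ready_low_salt_diet","low_salt_diet","encouragement","You seem ready to work on low salt diet - let's set a goal."
"ready_fluid_restriction","fluid_restriction","encouragement","You seem ready to work on fluid restriction - let's set a goal."
"ready_medication_intake","medication_intake","encouragement","You seem ready to work on medication intake - let's set a goal."
"congratulate","any","feedback_template","Well done - you reached your goal this week."
"consider_raising","any","feedback_template","You reached your goal and found it easy - consider a more ambitious goal."
"encourage_retry","any","feedback_template","You did not quite reach your goal - keep going next week."
"encourage_retry_or_raise","any","feedback_template","You missed your goal but found the sessions easy - try again, or adjust the plan."
"reduce_goal","any","feedback_template","That looked hard - consider setting a less ambitious goal for next week."
"contact_nurse","any","feedback_template","Reaching your goal keeps being difficult - please contact your heart failure nurse."
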