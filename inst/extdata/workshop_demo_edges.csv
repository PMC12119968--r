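group_id,cause,effect,polarity,delay,cause_is_action,effect_is_action
demo_workshop,trauma,substance_abuse,+,0,0,0
demo_workshop,substance_abuse,domestic_violence,+,0,0,0
demo_workshop,domestic_violence,trauma,+,0,0,0
demo_workshop,trauma,mental_health_stigma,-,0,0,0
demo_workshop,mental_health_stigma,dementia_risk,+,0,0,0
demo_workshop,substance_abuse,healthy_lifestyle,-,0,0,0
demo_workshop,healthy_lifestyle,chronic_disease_risk,-,0,0,0
demo_workshop,chronic_disease_risk,medication_side_effects,+,0,0,0
demo_workshop,medication_side_effects,dementia_risk,+,0,0,0
demo_workshop,chronic_disease_risk,dementia_risk,+,0,0,0
demo_workshop,health_literacy,knowledge_of_dementia_signs,+,0,0,0
demo_workshop,knowledge_of_dementia_signs,early_family_intervention,+,0,0,0
demo_workshop,early_family_intervention,family_caregiving,+,0,0,0
demo_workshop,family_caregiving,information_dissemination,+,0,0,0
demo_workshop,information_dissemination,health_literacy,+,0,0,0
demo_workshop,social_isolation,family_structure,-,0,0,0
demo_workshop,family_structure,positive_youth_behavior,+,0,0,0
demo_workshop,positive_youth_behavior,youth_hope,+,0,0,0
demo_workshop,youth_hope,crime_involvement,-,0,0,0
demo_workshop,crime_involvement,criminal_justice_bias,+,0,0,0
demo_workshop,criminal_justice_bias,convictions,+,0,0,0
demo_workshop,convictions,access_to_quality_jobs,-,0,0,0
demo_workshop,convictions,social_isolation,+,0,0,0
demo_workshop,access_to_quality_jobs,crime_involvement,-,0,0,0
demo_workshop,access_to_quality_jobs,income,+,0,0,0
demo_workshop,income,caregiving_quality,+,0,0,0
demo_workshop,caregiving_quality,dementia_risk,-,0,0,0
demo_workshop,dementia_risk,income,-,0,0,0
demo_workshop,health_literacy,ignorance,-,0,0,0
demo_workshop,ignorance,health_literacy,-,0,0,0
demo_workshop,poverty,dementia_risk,+,0,0,0
demo_workshop,dementia_risk,out_of_pocket_expenses,+,0,0,0
demo_workshop,out_of_pocket_expenses,poverty,+,0,0,0
demo_workshop,discriminatory_policies,school_funding,-,0,0,0
demo_workshop,school_funding,school_quality,+,0,0,0
demo_workshop,school_quality,education_level,+,0,0,0
demo_workshop,education_level,poverty,-,1,0,0
demo_workshop,poverty,political_apathy,+,0,0,0
demo_workshop,political_apathy,influence_on_policymakers,-,0,0,0
demo_workshop,influence_on_policymakers,discriminatory_policies,-,0,0,0
demo_workshop,dementia_risk,family_caregiving,+,0,0,0
demo_workshop,family_caregiving,health_literacy,+,0,0,0
demo_workshop,early_family_intervention,caregiving_quality,+,0,0,0
demo_workshop,health_literacy,mental_health_stigma,-,0,0,0
demo_workshop,mental_health_stigma,distress_anxiety,+,0,0,0
demo_workshop,distress_anxiety,dementia_risk,+,0,0,0
demo_workshop,education_level,mental_health_stigma,-,0,0,0
demo_workshop,education_level,health_literacy,+,0,0,0
demo_workshop,systemic_racism,redlining,+,0,0,0
demo_workshop,systemic_racism,poverty,+,0,0,0
demo_workshop,redlining,discriminatory_policies,+,0,0,0
demo_workshop,systemic_racism,police_response,+,0,0,0
demo_workshop,police_response,trauma,+,0,0,0
demo_workshop,information_campaign,health_literacy,+,0,1,0
demo_workshop,voter_mobilization,healthcare_access,+,0,1,0
demo_workshop,healthcare_access,dementia_risk,-,0,0,0
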