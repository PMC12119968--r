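raw,canonical
dementia,dementia_risk
risk of dementia,dementia_risk
health literacy,health_literacy
drug abuse,substance_abuse
substance use,substance_abuse
isolation,social_isolation
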