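[S2: personalized recommendation request]
Step 1: Identify the aspect of sleep or autonomic health the user wants to
improve.
Step 2: Relate it to the user's parameter values and cluster context.
Step 3: Propose concrete, prioritized behavioural recommendations.
Step 4: State what change in the parameters would indicate improvement.
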