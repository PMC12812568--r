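[Report generation path]
Step 1: List the seven sleep parameters with their units and compare each
value against its physiological reference range.
Step 2: Describe the sleep architecture (total, deep and light sleep, deep
sleep ratio) and what it implies for sleep quality.
Step 3: Describe autonomic state from the HRV metrics (SDNN, RMSSD, PNN50,
LF/HF), naming any clinically relevant events.
Step 4: Close with personalized, actionable suggestions consistent with the
findings; avoid diagnostic claims.
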