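[S3: general sleep-science question]
Step 1: Identify the physiological mechanism the question is about.
Step 2: Explain the mechanism in plain language (sleep stages, autonomic
balance, HRV), independent of any individual's values.
Step 3: Summarize the practical consequence and common misconceptions.
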