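[S1: interpretation of the user's own parameters]
Step 1: Identify which of the user's parameters the question refers to.
Step 2: Restate the user's value and its reference range.
Step 3: Explain what the value indicates for cardiac health, stress
resilience or sleep quality, in the context of the user's cluster.
Step 4: Answer the question directly; avoid diagnostic claims.
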