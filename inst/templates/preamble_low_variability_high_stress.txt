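[Cluster context: low variability, high stress]
This user shows reduced HRV (low SDNN and PNN50), suggesting possible stress
or autonomic imbalance. Prioritize stress management and lifestyle
adjustment in the reasoning.
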