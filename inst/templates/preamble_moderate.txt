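[Cluster context: moderate variability, moderate stress]
This user shows moderate HRV with patterns that may accompany sleep
irregularities (for example variable LF/HF balance). Explore sleep-related
issues through targeted questions and suggestions without implying a
clinical diagnosis.
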