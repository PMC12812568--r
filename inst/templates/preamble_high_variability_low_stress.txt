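[Cluster context: high variability, low stress]
This user shows elevated HRV (high RMSSD and PNN50), consistent with good
cardiac-autonomic health and low stress load. Emphasize maintaining current
habits and resolving minor concerns.
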