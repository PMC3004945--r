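trial_id: BIG1-98
arm: AI
endpoint: DFS
annual_rates: [0.0243, 0.0268, 0.0415, 0.0414, 0.0401]
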