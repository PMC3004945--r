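trial_id: ATAC
arm: AI
endpoint: EFS
annual_rates: [0.0127, 0.0212, 0.0229, 0.0212, 0.0200, 0.0200, 0.0209, 0.0217, 0.0203]
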