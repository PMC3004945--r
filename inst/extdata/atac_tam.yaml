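trial_id: ATAC
arm: TAM
endpoint: EFS
annual_rates: [0.0170, 0.0303, 0.0291, 0.0269, 0.0283, 0.0285, 0.0264, 0.0242, 0.0279]
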