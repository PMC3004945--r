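trial_id: BIG1-98
arm: TAM
endpoint: DFS
annual_rates: [0.0264, 0.0460, 0.0469, 0.0481, 0.0397]
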