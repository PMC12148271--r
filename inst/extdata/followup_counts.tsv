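study	n_baseline_hc	n_followup_sud
ABCD	11085	1930
IMAGEN	987	549
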