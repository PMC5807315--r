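label,no_cluster,small,medium,large
Hs578T (Control),1.6,58.3,13.4,26.7
Hs578T with Methylene Blue,0.5,43.0,25.7,30.8
Hs578T with Fructose-1-6-Bisphosphate,0.0,45.3,29.1,25.6
Hs578T with Epidermal Growth Factor,0.4,53.1,7.6,38.9
Hs578T with 2-Deoxyglucose,0.0,34.7,21.2,44.1
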