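trait,p1,p2,p3,p4,published_label
Total fat pad weight,0.017,5.7e-07,0.081,0.76,causal_marginal
Inguinal fat pad weight,0.014,6.6e-07,0.061,0.71,causal_marginal
Gonadal fat pad weight,0.068,1.3e-07,0.055,0.43,not_causal
Perirenal fat pad weight,0.0063,9.7e-07,0.54,0.39,not_causal
Liver weight,0.82,2.7e-08,0.32,0.44,not_causal
Kidney weight,0.051,1.9e-07,0.73,0.51,not_causal
Heart weight,0.28,5.8e-08,0.90,0.69,not_causal
Lung weight,0.024,2.6e-07,0.88,0.33,not_causal
Spleen weight,0.050,2.3e-07,0.43,0.78,not_causal
Testis weight,0.31,2.0e-08,0.26,0.15,not_causal
Adjusted total fat pad weight,0.0074,1.0e-06,0.022,0.55,causal
Adjusted inguinal fat pad weight,0.0045,1.4e-06,0.008,0.43,causal
Adjusted gonadal fat pad weight,0.22,3.6e-08,0.047,0.24,not_causal
Adjusted perirenal fat pad weight,5.7e-04,1.1e-06,0.61,0.029,not_causal
Adjusted liver weight,0.27,3.5e-08,0.52,0.28,not_causal
Adjusted kidney weight,0.0018,3.1e-06,0.34,0.42,not_causal
Adjusted heart weight,0.047,2.2e-07,0.55,0.65,not_causal
Adjusted lung weight,0.011,5.1e-07,0.76,0.31,not_causal
Adjusted spleen weight,0.013,7.1e-07,0.26,0.78,not_causal
Adjusted testis weight,0.50,1.3e-08,0.17,0.13,not_causal
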