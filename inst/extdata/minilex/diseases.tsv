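# Disease terms (surface <TAB> identifier).
IPF	ipf
idiopathic pulmonary fibrosis	ipf
pulmonary fibrosis	pulmonary fibrosis
lung fibrosis	lung fibrosis
interstitial pneumonia	interstitial pneumonia
asthma	asthma
COPD	copd
emphysema	emphysema
sarcoidosis	sarcoidosis
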