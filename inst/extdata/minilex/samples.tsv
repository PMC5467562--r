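# Sample descriptors: tissue and cell types plus patient variables.
lung tissue
lung biopsies
lung biopsy
fibroblasts
lung fibroblasts
alveolar macrophages
epithelial cells
alveolar epithelial cells
serum
plasma
peripheral blood
sputum
female
male
smokers
non-smokers
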