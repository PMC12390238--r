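name,abbreviation,cas_number,molecular_formula,molecular_weight,solubility_mg_L,log_kow,log_koc,half_life_d,bcf
Bisphenol A,BPA,80-05-7,C15H16O2,228.29,300,3.41,4.88,37.5,71.9
Bisphenol S,BPS,80-09-1,C12H10O4S,250.27,1100,1.65,2.5,37.5,3.16
Bisphenol F,BPF,620-92-8,C13H12O2,200.24,540,2.91,4.47,15,34.7
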