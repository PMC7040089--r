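wavelength_nm,eps_hbo2,eps_hb,units,source
760,586.0,1548.52,M^-1 cm^-1 (log10),compiled in-vivo NIR hemoglobin spectra (Prahl/Cope tabulation)
830,974.0,693.04,M^-1 cm^-1 (log10),compiled in-vivo NIR hemoglobin spectra (Prahl/Cope tabulation)
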