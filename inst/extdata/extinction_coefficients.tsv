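# Molar (decadic) extinction coefficients of oxy- and deoxyhaemoglobin,
# units cm^-1 / (mol L^-1), at the two device wavelengths.
# Source: compiled haemoglobin absorption spectra, S. Prahl, Oregon Medical
# Laser Center (1998), https://omlc.org/spectra/hemoglobin/
# table version: 1.0
wavelength_nm	hbo	hbr
760	586.0	1548.52
850	1058.0	691.32
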