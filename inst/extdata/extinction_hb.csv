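# Molar extinction coefficients of oxy- and deoxyhemoglobin (base-10,
# cm^-1 / (mol/L)), from the widely redistributed Gratzer/Prahl tabulation
# (S. Prahl, "Optical absorption of hemoglobin", OMLC). Values at
# intermediate wavelengths are obtained by linear interpolation in code.
wavelength_nm,eps_hbo_cm_M,eps_hbr_cm_M
690,276.0,2051.96
900,1198.0,761.84
910,1213.76,723.52
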