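# Physical constants (SI)
FARADAY <- 96485.33        # C/mol
GAS_CONSTANT <- 8.314      # J/mol/K
CARBON_MOLAR_MASS <- 12.011  # g/mol
VACUUM_PERMITTIVITY <- 8.8541878128e-12  # F/m
LMH_PER_M_S <- 3.6e6       # (L m^-2 h^-1) per (m/s)
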