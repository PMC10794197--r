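# Property-model configuration: specifiers are surface patterns (seeded with
# the symbols and common variants used in the TADF literature), allowed units
# carry multiplicative factors to the standard unit. Energy accepts kJ/mol
# with 1 eV = 96.485 kJ/mol.
lambda_em:
  dimension: length
  standard_unit: nm
  specifiers:
    - "λem"
    - "λEM"
    - "λ em"
    - "λmax(em)"
    - "λmax,em"
    - "λmax"
    - "λPL"
    - "emission maximum"
    - "maximum emission wavelength"
    - "emission wavelength"
    - "emission peak"
  allowed_units:
    - {symbol: "nm", factor: 1}
    - {symbol: "μm", factor: 1000}
    - {symbol: "Å", factor: 0.1}
  extra_fields: [phase]
plqy:
  dimension: dimensionless-fraction
  standard_unit: "%"
  specifiers:
    - "ΦPL"
    - "Φ PL"
    - "Φf"
    - "ΦF"
    - "PLQY"
    - "photoluminescence quantum yield"
    - "quantum yield"
  allowed_units:
    - {symbol: "%", factor: 1}
  extra_fields: [phase, atmosphere]
delta_e_st:
  dimension: energy
  standard_unit: eV
  specifiers:
    - "ΔEST"
    - "ΔE ST"
    - "ΔEst"
    - "ΔE(S1-T1)"
    - "ΔE(S1−T1)"
    - "singlet-triplet energy splitting"
    - "singlet-triplet splitting"
    - "singlet-triplet gap"
  allowed_units:
    - {symbol: "eV", factor: 1}
    - {symbol: "meV", factor: 0.001}
    - {symbol: "kJ/mol", factor_inverse: 96.485}
  extra_fields: [is_experimental]
tau_d:
  dimension: time
  standard_unit: "μs"
  specifiers:
    - "τd"
    - "τD"
    - "τ d"
    - "τdelayed"
    - "τDF"
    - "delayed lifetime"
    - "delayed fluorescence lifetime"
  allowed_units:
    - {symbol: "s", factor: 1000000}
    - {symbol: "ms", factor: 1000}
    - {symbol: "μs", factor: 1}
    - {symbol: "us", factor: 1}
    - {symbol: "ns", factor: 0.001}
    - {symbol: "ps", factor: 0.000001}
  extra_fields: [temperature]
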