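# package-wide constants (collated first)

DAYS_PER_YEAR <- 365.25
HALF_DAY <- 0.5 / DAYS_PER_YEAR
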