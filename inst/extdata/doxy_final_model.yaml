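# Final population model for doxycycline disposition in pigs.
# Typical values at the 50-kg reference body weight; BSV given as CV%
# (converted to log-scale omegas at load time).
disposition:
  Cl: 0.259     # L/kg/h
  Cl2: 1.179
  Cl3: 0.072
  Vc: 0.192     # L/kg
  V2: 0.595
  V3: 0.536
covariates:      # allometric body-weight power exponents, reference 50 kg
  Cl: 0.299
  Cl2: -0.224
  Cl3: -0.544
  V3: 0.376
absorption:
  FEED_TLS:      # in-feed, field conditions
    Ka: 0.072    # 1/h
    F: 0.501
  FEED_OTHERS:   # in-feed, laboratory conditions
    Ka: 0.144
    F: 0.340
  SOL_DW:        # solution in drinking water
    Ka: 0.689
    F: 0.307
  SOL_TUBING:    # solution by stomach tube
    Ka: 0.725
    F: 0.258
bsv_percent:
  Cl: 27.1
  Cl2: 80.0
  Cl3: 245.5
  Vc: 107.8
  V2: 63.4
  V3: 47.5
  Ka_FEED_TLS: 16.9
  F_FEED_TLS: 84.8
  Ka_FEED_OTHERS: 51.4
  F_FEED_OTHERS: 36.4
  Ka_SOL_DW: 27.6
  F_SOL_DW: 34.3
  Ka_SOL_TUBING: 54.0
  F_SOL_TUBING: 29.3
residual:        # additive SD (ug/mL) + proportional SD (fraction)
  IV:
    stdev0: 0.013
    cmult: 0.139
  FEED_TLS:
    stdev0: 0.113
    cmult: 0.228
  FEED_OTHERS:
    stdev0: 0.019
    cmult: 0.184
  SOL_DW:
    stdev0: 0.006
    cmult: 0.293
  SOL_TUBING:
    stdev0: 0.003
    cmult: 0.275
ref_bw: 50
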