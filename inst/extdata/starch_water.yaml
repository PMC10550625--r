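# Reference configuration: a water-swollen starch microsphere in water.
fluid:
  rho_f: 0.997
  mu_f: 0.89
  g: 9.87
  units: {rho_f: g/cm3, mu_f: mPa.s}
particle:
  d_p: 500
  delta_rho: 49.85
  units: {d_p: um}
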