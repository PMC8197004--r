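# Example configuration for rem-oxsim. Any key omitted here keeps the
# package default (the reference parameter set). SI units throughout, except
# the explicitly suffixed convenience keys shown below.
species:
  toc_mgC_per_L: 141          # feed total organic carbon
flow:
  tmp_mbar: 40                # transmembrane pressure
  zeta_mV: -22                # pore-surface zeta potential
  sigma: 1.6e-14              # Darcy permeability, m2
  blockage_exponent: 0.6666666666666666
gas:
  k_v: 6.0e-4                 # gas/solution mass-transfer coefficient, 1/s
  k_g: 0.07                   # volatility coefficient, m3/mol
electro:
  i_tot_schedule:
    - {t_start_min: 0, t_end_min: 90, i_tot: -300}
    - {t_start_min: 90, t_end_min: 140, i_tot: 0}
geometry:
  n_cells_dl: 8
  n_cells_rem: 60
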