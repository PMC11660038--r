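# shared fixtures built in code

# exact two-segment series on a linear abscissa, kink at `cmc`
make_vshape <- function(cmc = 0.5, pre = -30, post = 2, y0 = 45,
                        conc = seq(0.1, 1, length.out = 13),
                        technique = "conductivity") {
  d <- conc - cmc
  y <- y0 + ifelse(d <= 0, pre * d, post * d)
  titration_series(conc, y, technique = technique)
}

# worked-example constants (printed instrument summaries)
WX <- list(
  slope_rgds = -10.8e-3, slope_grds = -13.9e-3,  # N/m per ln c
  temperature = 293,                             # K
  radius = 14,                                   # A, micelle core
  i0_grds = 0.11, i0_rgds = 0.06,                # cm^-1
  conc_wt = 1,                                   # wt%
  m_mol_grds = 1376.7, m_mol_rgds = 1376.5       # g/mol
)
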