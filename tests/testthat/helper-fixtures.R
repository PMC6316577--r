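# shared fixture builders; everything generated in code, nothing on disk

gaussian_trace <- function(w, center, height, fwhm = 20) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  height * exp(-(w - center)^2 / (2 * sigma^2))
}

# synthetic D2 parameter set with easy numbers for closed-form checks:
# pair_dispersion converts C6 from J nm^6/mol to kJ mol^-1 A^6 by a factor
# 1e3, so dividing it out makes the effective pair C6 products 1, 4, 9
toy_d2 <- function(s6 = 1, d = 20, cutoff = 30, r = 0.5) {
  d2_params(c6 = c(H = 1 / 1e3, O = 4 / 1e3, N = 9 / 1e3),
            r_vdw = c(H = r, O = r, N = r),
            s6 = s6, d = d, cutoff = cutoff)
}

cluster3 <- function(cell = NULL) {
  structure3d(c("O", "H", "H"),
              rbind(c(0, 0, 0), c(2.2, 0, 0), c(0, 2.4, 0.3)),
              cell = cell)
}

energy_table_text <- function() c(
  "name,coverage,topology,dE_c,dE_disp,dH_c,dG_c",
  "SiO2-FA1,LC,monomer,-69.9,-18.8,-62.8,-13.3",
  "SiO2-FA2,LC,monomer,-44.0,-28.1,-38.1,8.6",
  "SiO2-FA3,LC,monomer,-68.0,-26.4,-60.7,-9.6",
  "SiO2-FA4,LC,monomer,-80.5,-27.4,-74.2,-21.3",
  "SiO2-FA5,LC,monomer,-63.3,-15.6,-56.8,-19.3")
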