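# shared fixtures and independent oracles

ccd_fixture <- function() read_design_table(fbd_fixture("table2_ccd.csv"))

study_factors <- function() list(
  doe_factor("Methanol concentration", "A", 10, 20, 30, "% v/v"),
  doe_factor("Mobile phase pH", "B", 2.5, 3.5, 4.0, "pH"))

# brute-force normal-equations solve for the two-factor quadratic,
# independent of the package's fitting path
normal_eq_quadratic <- function(x1, x2, y) {
  X <- cbind(1, x1, x2, x1 * x2, x1^2, x2^2)
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# count of each level pair across a pair of columns (orthogonality oracle)
pair_counts <- function(m, i, j) table(paste(m[, i], m[, j]))

# forward mass-balance dissolution simulator: given true cumulative
# released mass (ug) at each sample time, produce the aliquot
# concentrations an analyst would actually measure when each sample
# removes va mL replaced by fresh buffer
sampled_concentrations <- function(mass_released, vm, va) {
  conc <- numeric(length(mass_released))
  removed <- 0
  for (n in seq_along(mass_released)) {
    conc[n] <- (mass_released[n] - removed) / vm
    removed <- removed + va * conc[n]
  }
  conc
}
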