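# Independent mass-balance oracle for the binding isotherm: bisection on the
# bound-protein concentration b in [0, min(c_A, N c_B)], solving
#   (c_A - b) * (N c_B - b) = K_D * b
# (free protein times free sites equals K_D times bound). Parameterizing in b
# keeps the bound fraction b/c_A accurate even when it is tiny.
bound_fraction_oracle <- function(c_A, c_B, N, K_D) {
  if (c_B == 0) return(0)
  g <- function(b) (c_A - b) * (N * c_B - b) - K_D * b
  lo <- 0
  hi <- min(c_A, N * c_B)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / c_A
}

# Construct an epitope_map directly from a class vector (for consensus-rule
# tests where only the classes matter).
make_class_map <- function(classes, label = "L") {
  df <- data.frame(residue_index = seq_along(classes),
                   residue_code = "X",
                   delta_comb = 0,
                   status = ifelse(classes == "disappeared-high",
                                   "disappeared", "measured"))
  df$class <- factor(classes, levels = nmrbind:::.csp_classes)
  structure(df, class = c("epitope_map", "data.frame"),
            sigma0 = 0.1, ligand_label = label)
}
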