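# Shared fixtures, built in code.

# tiny hand-specified table: 4 features x 4 samples (2 mothers, 2 infants)
tiny_table <- function() {
  feature_table(matrix(
    c(5, 0, 2, 1,   # asv1
      0, 3, 0, 4,   # asv2
      2, 2, 1, 0,   # asv3
      0, 0, 7, 5),  # asv4
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("asv", 1:4), c("M1", "M2", "I1", "I2"))
  ))
}

tiny_metadata <- function() {
  data.frame(
    sample_id = c("M1", "M2", "I1", "I2"),
    subject_id = c("m1", "m2", "i1", "i2"),
    role = c("mother", "mother", "infant", "infant"),
    pair_id = c(NA, NA, "M1", "M2"),
    feeding = c(NA, NA, "breast", "formula"),
    stringsAsFactors = FALSE
  )
}

# random valid count table for property-style loops
random_table <- function(n_feat = 5, n_samp = 5, lambda = 4) {
  repeat {
    m <- matrix(stats::rpois(n_feat * n_samp, lambda), n_feat, n_samp,
                dimnames = list(paste0("f", seq_len(n_feat)),
                                paste0("s", seq_len(n_samp))))
    if (all(colSums(m) > 0)) return(feature_table(m))
  }
}

# brute-force Bray-Curtis on two profiles (independent of the implementation)
bc_brute <- function(x, y) sum(abs(x - y)) / sum(x + y)

quick_sim <- function(...) simulate_cohort(sim_config(...))
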