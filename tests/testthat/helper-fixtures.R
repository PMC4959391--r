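# shared fixtures built in code

# small fast design for structural tests
tiny_design <- function(alpha = 0.05, ...) {
  # joint and orthogonal loading bumps well separated, as in the reference
  # designs, so the generative parts are nearly uncorrelated in variable space
  sim_design(N = 120, p = 24, q = 18,
             profiles = list(W = c(18, 2.5), C = c(14, 2),
                             P_Yorth = c(6, 2.5), P_Xorth = c(4, 2)),
             alpha = alpha, ...)
}

# principal angle between the column spans of two single-column matrices
principal_angle <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))))
}

random_paired <- function(seed, N = 60, p = 10, q = 8) {
  set.seed(seed)
  paired_omics(matrix(rnorm(N * p), N, p), matrix(rnorm(N * q), N, q),
               center = TRUE)
}
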