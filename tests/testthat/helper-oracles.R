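# Independent textbook implementations used as oracles. These deliberately
# share no code with the package internals.

# full-matrix dynamic-programming alignment distance
dtw_ref <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- abs(outer(a, b, "-"))
  C <- matrix(NA_real_, n, m)
  C[1, 1] <- D[1, 1]
  for (i in seq_len(n)[-1]) C[i, 1] <- C[i - 1, 1] + D[i, 1]
  for (j in seq_len(m)[-1]) C[1, j] <- C[1, j - 1] + D[1, j]
  if (n > 1 && m > 1)
    for (i in 2:n) for (j in 2:m)
      C[i, j] <- D[i, j] + min(C[i - 1, j], C[i, j - 1], C[i - 1, j - 1])
  C[n, m]
}

# small homogeneous block + 2x2 plan, cheap enough for per-pose checks
tiny_setup <- function(gray = 500) {
  vol <- ct_volume(array(gray, dim = c(32, 32, 20)), spacing = 0.25)
  plan <- milling_plan(n_layers = 2, n_paths = 2, path_length = 4,
                       origin = c(2, 2.5, 5))
  list(vol = vol, plan = plan, spec = cutter_spec(),
       coeffs = force_coefficients(), norm = norm_params())
}
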