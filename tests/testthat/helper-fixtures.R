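# Shared fixtures built in code so the repository stays free of binary
# or bulky data files.

# A minimal classic-DSSP residue table. Fixed columns (1-based):
#   1-5  sequential residue number ('#' column)
#   14   one-letter amino acid ('!' at chain breaks)
#   17   secondary structure summary
#   26-29 BP1, 30-33 BP2 (bridge partners, DSSP numbering, 0 = none)
# Two strands, residues 2-4 and 8-10 (1-based DSSP numbers), forming an
# antiparallel ladder: 2-10, 3-9, 4-8.
dssp_fixture_lines <- function() {
  hdr <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE ...",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    NULL)
  row <- function(num, aa, ss, bp1, bp2) {
    line <- sprintf("%5d %4d A", num, num)    # cols 1-5 num, then resnum/chain
    line <- sprintf("%-13s", line)
    line <- paste0(line, aa)                   # col 14
    line <- sprintf("%-16s", line)
    line <- paste0(line, ss)                   # col 17
    line <- sprintf("%-25s", line)
    paste0(line, sprintf("%4d%4d", bp1, bp2))  # cols 26-29, 30-33
  }
  c(hdr,
    row(1, "M", " ", 0, 0),
    row(2, "V", "E", 10, 0),
    row(3, "K", "E", 9, 0),
    row(4, "L", "E", 8, 0),
    row(5, "G", " ", 0, 0),
    row(6, "S", " ", 0, 0),
    row(7, "T", " ", 0, 0),
    row(8, "I", "E", 4, 0),
    row(9, "F", "E", 3, 0),
    row(10, "A", "E", 2, 0),
    row(11, "D", " ", 0, 0))
}

# A small deterministic symmetric map with values in [0, 1].
toy_symmetric_map <- function(L, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(L * L), L, L)
  (m + t(m)) / 2
}

# Noise-free simulation parameters at a fixed length.
noiseless_params <- function(L = 40L, n_strands = c(2L, 3L)) {
  simulation_params(length_range = c(L, L), n_strand_range = n_strands,
                    fp_density = 0, miss_rate = 0, blur_sigma = 0,
                    ss_error_rate = 0)
}

# Direct reimplementation of the scale-space ridge features used as an
# independent oracle: shift-based separable Gaussian smoothing with
# symmetric (edge-repeating) reflection, finite-difference Hessian,
# per-pixel eigen().
ridge_oracle <- function(m, scales = c(1, 2, 4), gamma = 0.75) {
  L <- nrow(m)
  reflect <- function(idx) {
    # symmetric reflection including the edge sample: ... b a | a b c ...
    while (any(idx < 1L | idx > L)) {
      idx <- ifelse(idx < 1L, 1L - idx, idx)
      idx <- ifelse(idx > L, 2L * L + 1L - idx, idx)
    }
    idx
  }
  smooth2d <- function(mat, t) {
    sigma <- sqrt(t)
    r <- max(1L, ceiling(4 * sigma))
    k1 <- exp(-((-r:r)^2) / (2 * t))
    k1 <- k1 / sum(k1)
    rows <- matrix(0, L, L)
    for (a in -r:r) {
      rows <- rows + k1[a + r + 1] * mat[reflect(seq_len(L) + a), ]
    }
    out <- matrix(0, L, L)
    for (b in -r:r) {
      out <- out + k1[b + r + 1] * rows[, reflect(seq_len(L) + b)]
    }
    out
  }
  d2 <- function(v) {
    n <- length(v)
    if (n < 3) return(rep(0, n))
    out <- numeric(n)
    out[2:(n - 1)] <- v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]
    out[1] <- v[3] - 2 * v[2] + v[1]
    out[n] <- v[n] - 2 * v[n - 1] + v[n - 2]
    out
  }
  d1 <- function(v) {
    n <- length(v)
    if (n < 2) return(rep(0, n))
    out <- numeric(n)
    if (n >= 3) out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    out[1] <- v[2] - v[1]
    out[n] <- v[n] - v[n - 1]
    out
  }
  height <- matrix(0, L, L)
  theta <- matrix(0, L, L)
  for (t in scales) {
    sm <- smooth2d(m, t)
    hxx <- apply(sm, 2, d2)                 # second difference down rows
    hyy <- t(apply(sm, 1, d2))              # along columns
    hxy <- apply(t(apply(sm, 1, d1)), 2, d1)
    for (i in seq_len(L)) for (j in seq_len(L)) {
      H <- matrix(c(hxx[i, j], hxy[i, j], hxy[i, j], hyy[i, j]), 2, 2)
      ev <- eigen(H, symmetric = TRUE)
      lam1 <- min(ev$values)
      s <- t^gamma * max(0, -lam1)
      if (s > height[i, j]) {
        height[i, j] <- s
        v <- ev$vectors[, which.min(ev$values)]
        if (abs(hxx[i, j]) < 1e-14 && abs(hyy[i, j]) < 1e-14 &&
            abs(hxy[i, j]) < 1e-14) {
          v <- c(1, 0)
        }
        theta[i, j] <- atan2(v[2], v[1]) %% pi
      }
    }
  }
  list(height = height, theta = theta)
}
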