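#' Ridge-detection parameters
#'
#' Scale-space settings for the gamma-normalized ridge detector. `scales`
#' are the scale-space variances t (pixel^2 units) at which the map is
#' smoothed; `gamma` is the normalization exponent that makes ridge
#' strength comparable across scales. Beta-strand ridges on a contact map
#' are one to two pixels wide, so small scales suffice; gamma = 3/4 is
#' the standard choice for ridge (as opposed to blob or edge) detection.
#'
#' @param scales Strictly increasing positive reals.
#' @param gamma Normalization exponent in (0, 2].
#' @return An object of class `"ridge_params"`.
#' @export
ridge_params <- function(scales = c(1, 2, 4), gamma = 0.75) {
  scales <- as.numeric(scales)
  if (length(scales) == 0L || any(scales <= 0) ||
      any(diff(scales) <= 0)) {
    stop("scales must be nonempty, positive and strictly increasing")
  }
  if (gamma <= 0 || gamma > 2) stop("gamma must lie in (0, 2]")
  structure(list(scales = scales, gamma = gamma), class = "ridge_params")
}

# 1D Gaussian smoothing operator with symmetric (reflective) boundary,
# returned as a dense L x L matrix so that smoothing is K %*% M %*% t(K).
# The kernel has standard deviation sqrt(t) and is truncated at 4*sqrt(t).
gaussian_operator <- function(L, t) {
  sigma <- sqrt(t)
  r <- max(1L, ceiling(4 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * t))
  g <- g / sum(g)
  K <- matrix(0, L, L)
  for (k in seq(-r, r)) {
    w <- g[k + r + 1L]
    for (i in seq_len(L)) {
      j <- i + k
      # symmetric reflection including the edge sample: ... c b a | a b c ...
      while (j < 1L || j > L) {
        if (j < 1L) j <- 1L - j
        if (j > L) j <- 2L * L + 1L - j
      }
      K[i, j] <- K[i, j] + w
    }
  }
  K
}

#' Gaussian scale-space smoothing
#'
#' Separable Gaussian smoothing of a 2D map with standard deviation
#' `sqrt(t)`, kernel truncated at `4 * sqrt(t)`, reflective boundary
#' handling. Constant maps are preserved exactly (the kernel is
#' renormalized after truncation).
#'
#' @param m Numeric matrix.
#' @param t Scale-space variance, t > 0.
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_scale_space <- function(m, t) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("t must be > 0")
  Kr <- gaussian_operator(nrow(m), t)
  Kc <- if (ncol(m) == nrow(m)) Kr else gaussian_operator(ncol(m), t)
  Kr %*% m %*% t(Kc)
}

# Derivative operators on a 1D grid (unit spacing): second difference with
# one-sided (shifted) stencils at the borders, first difference with
# one-sided stencils at the borders. Applied along rows via matrix product.
second_diff_operator <- function(L) {
  D <- matrix(0, L, L)
  if (L < 3L) stop("need L >= 3 for second differences")
  for (i in 2:(L - 1L)) D[i, (i - 1L):(i + 1L)] <- c(1, -2, 1)
  D[1, 1:3] <- c(1, -2, 1)
  D[L, (L - 2L):L] <- c(1, -2, 1)
  D
}

first_diff_operator <- function(L) {
  D <- matrix(0, L, L)
  for (i in 2:(L - 1L)) {
    D[i, i - 1L] <- -0.5
    D[i, i + 1L] <- 0.5
  }
  D[1, 1:2] <- c(-1, 1)
  D[L, (L - 1L):L] <- c(-1, 1)
  D
}

#' Per-pixel Hessian eigen-decomposition
#'
#' Computes the 2x2 Hessian of a smoothed map by finite differences
#' (central second differences at interior pixels, one-sided stencils at
#' the borders) and its eigenvalues `lambda1 <= lambda2` with the
#' orientation `theta` in \[0, pi) of the eigenvector of `lambda1` — the
#' across-ridge direction, measured from the first (row) axis.
#'
#' @param m Numeric matrix (at least 3 x 3).
#' @return List with matrices `lambda1`, `lambda2`, `theta`.
#' @export
hessian_eigen <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  L1 <- nrow(m); L2 <- ncol(m)
  if (L1 < 3L || L2 < 3L) stop("need at least a 3 x 3 map")
  D2r <- second_diff_operator(L1)
  D2c <- second_diff_operator(L2)
  D1r <- first_diff_operator(L1)
  D1c <- first_diff_operator(L2)
  hxx <- D2r %*% m                 # d2/di2, along rows of the first axis
  hyy <- m %*% t(D2c)              # d2/dj2
  hxy <- D1r %*% m %*% t(D1c)      # mixed derivative
  half_tr <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  lambda1 <- half_tr - disc
  lambda2 <- half_tr + disc
  # eigenvector of lambda1: (hxy, lambda1 - hxx), with degenerate fallback
  vx <- hxy
  vy <- lambda1 - hxx
  flat <- abs(vx) < 1e-14 & abs(vy) < 1e-14
  # when hxy ~ 0 the axes are the eigenvectors; lambda1 is the smaller of
  # hxx, hyy so the across-ridge direction is the corresponding axis
  vx[flat] <- as.numeric(hxx[flat] <= hyy[flat])
  vy[flat] <- as.numeric(hxx[flat] > hyy[flat])
  theta <- atan2(vy, vx) %% pi
  list(lambda1 = lambda1, lambda2 = lambda2, theta = theta)
}

#' Gamma-normalized ridge strength
#'
#' Bright-ridge strength at scale t: `S = t^gamma * max(0, -lambda1)`.
#' Contacts are high values, so only negative across-ridge curvature
#' (bright ridges) contributes; valleys score zero.
#'
#' @param lambda1 Matrix of smaller Hessian eigenvalues at scale `t`.
#' @param t Scale-space variance.
#' @param gamma Normalization exponent.
#' @return Nonnegative matrix of ridge strengths.
#' @export
ridge_strength <- function(lambda1, t, gamma) {
  t^gamma * pmax(0, -lambda1)
}

#' Ridge map
#'
#' Container for the ridge features of a contact map: the gamma-normalized
#' ridge `height` (maximum strength over scales) and the ridge direction
#' encoded as height-weighted double-angle channels
#' `cos2 = h * cos(2 theta)` and `sin2 = h * sin(2 theta)`, where `h` is
#' the height normalized by its maximum over the map. Doubling the angle
#' removes the theta vs theta + pi ambiguity of an undirected ridge;
#' weighting by normalized height suppresses meaningless directions in
#' flat regions.
#'
#' @param height Nonnegative L x L matrix.
#' @param cos2,sin2 Direction channels in \[-1, 1\], zero where height is 0.
#' @return An object of class `"ridge_map"`.
#' @export
ridge_map <- function(height, cos2, sin2) {
  stopifnot(is.matrix(height), all(dim(height) == dim(cos2)),
            all(dim(height) == dim(sin2)))
  if (any(height < 0)) stop("ridge height must be nonnegative")
  structure(list(length = nrow(height), height = height,
                 cos2 = cos2, sin2 = sin2), class = "ridge_map")
}

#' @export
print.ridge_map <- function(x, ...) {
  cat(sprintf("Ridge map: L = %d, max height %.4g\n", x$length,
              max(x$height)))
  invisible(x)
}

#' Compute scale-space ridge features of a contact map
#'
#' For each scale t the map is Gaussian-smoothed, the per-pixel Hessian
#' eigen-system computed, and the gamma-normalized bright-ridge strength
#' `t^gamma * max(0, -lambda1)` evaluated. The per-pixel height is the
#' maximum over scales and the orientation is taken from the maximizing
#' scale (first scale on ties). Direction channels are the normalized
#' height times `cos(2 theta)` and `sin(2 theta)`.
#'
#' A contiguous anti-diagonal ridge (an antiparallel strand pairing)
#' yields `theta ~ 45` degrees, i.e. `sin(2 theta) ~ 1`; a diagonal ridge
#' (parallel pairing) yields `sin(2 theta) ~ -1`.
#'
#' @param map A [contact_map()] or plain matrix.
#' @param params A [ridge_params()].
#' @return A [ridge_map()].
#' @export
compute_ridge_features <- function(map, params = ridge_params()) {
  m <- if (inherits(map, "contact_map")) map$values else as.matrix(map)
  stopifnot(inherits(params, "ridge_params"))
  L <- nrow(m)
  height <- matrix(0, L, L)
  theta <- matrix(0, L, L)
  for (t in params$scales) {
    sm <- gaussian_scale_space(m, t)
    he <- hessian_eigen(sm)
    S <- ridge_strength(he$lambda1, t, params$gamma)
    better <- S > height
    height[better] <- S[better]
    theta[better] <- he$theta[better]
  }
  hmax <- max(height)
  hnorm <- if (hmax > 0) height / hmax else height
  nz <- height > 0
  cos2 <- matrix(0, L, L)
  sin2 <- matrix(0, L, L)
  cos2[nz] <- hnorm[nz] * cos(2 * theta[nz])
  sin2[nz] <- hnorm[nz] * sin(2 * theta[nz])
  ridge_map(height, cos2, sin2)
}
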