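#' Simulation parameters for synthetic beta-sheet proteins
#'
#' Defaults describe a desk-scale regime: chains of 50-120 residues with
#' 2-6 strands, sparse false-positive contacts (1% of empty off-band
#' cells at strength 0.3-1), 10% missed true pairs, mild blur
#' (sigma = 0.5 pixels) and 10% secondary-structure assignment errors.
#'
#' @param length_range Integer range (min, max) of protein lengths.
#' @param n_strand_range Integer range of strand counts.
#' @param fp_density Probability that an empty off-band cell receives a
#'   false-positive contact, in \[0, 1).
#' @param miss_rate Probability that a true pair is erased, in \[0, 1).
#' @param blur_sigma Gaussian blur standard deviation (pixels), >= 0.
#' @param ss_error_rate Probability that a residue's strand/coil
#'   assignment is flipped in the simulated profile, in \[0, 1).
#' @param n_homologs_range Range for the log-uniform alignment depth.
#' @return An object of class `"simulation_params"`.
#' @export
simulation_params <- function(length_range = c(50L, 120L),
                              n_strand_range = c(2L, 6L),
                              fp_density = 0.01, miss_rate = 0.1,
                              blur_sigma = 0.5, ss_error_rate = 0.1,
                              n_homologs_range = c(10, 10000)) {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            length(n_strand_range) == 2L,
            n_strand_range[1] <= n_strand_range[2],
            fp_density >= 0, fp_density < 1,
            miss_rate >= 0, miss_rate < 1,
            blur_sigma >= 0,
            ss_error_rate >= 0, ss_error_rate < 1,
            length(n_homologs_range) == 2L,
            n_homologs_range[1] > 0,
            n_homologs_range[1] <= n_homologs_range[2])
  structure(list(length_range = as.integer(length_range),
                 n_strand_range = as.integer(n_strand_range),
                 fp_density = fp_density, miss_rate = miss_rate,
                 blur_sigma = blur_sigma, ss_error_rate = ss_error_rate,
                 n_homologs_range = as.numeric(n_homologs_range)),
            class = "simulation_params")
}

#' Sheet topology
#'
#' Planted strands and their pairings. Strands are `(start, length)` in
#' 0-based residue coordinates, non-overlapping and separated by at
#' least two loop residues, each 3-10 residues long. Pairings form
#' chains (every strand pairs with at most two neighbours), with a
#' uniform parallel/antiparallel orientation and an integer register.
#' For a parallel pairing, strand-A position p pairs with strand-B
#' position `p + register`; for an antiparallel pairing, with
#' `register - p`. The register is drawn so the aligned overlap spans
#' at least 3 residues.
#'
#' @param length Protein length L.
#' @param strands Two-column matrix `(start, length)`.
#' @param pairings Data frame with columns `a`, `b` (strand indices,
#'   1-based), `orientation` (`"parallel"`/`"antiparallel"`),
#'   `register`.
#' @return An object of class `"sheet_topology"`.
#' @export
sheet_topology <- function(length, strands, pairings) {
  length <- as.integer(length)
  if (is.null(strands) || NROW(strands) == 0L) {
    strands <- matrix(integer(0), ncol = 2)
  } else {
    strands <- matrix(as.integer(as.matrix(strands)), ncol = 2)
  }
  dimnames(strands) <- list(NULL, c("start", "length"))
  if (nrow(strands) > 0) {
    if (any(strands[, 2] < 3L) || any(strands[, 2] > 10L)) {
      stop("strand lengths must lie in [3, 10]")
    }
    ends <- strands[, 1] + strands[, 2] - 1L
    if (any(strands[, 1] < 0L) || any(ends >= length)) {
      stop("strand outside the chain")
    }
    ord <- order(strands[, 1])
    if (nrow(strands) > 1L) {
      gaps <- strands[ord[-1], 1] - (ends[ord[-nrow(strands)]] + 1L)
      if (any(gaps < 2L)) stop("strands must be separated by >= 2 loop residues")
    }
  }
  if (is.null(pairings)) {
    pairings <- data.frame(a = integer(0), b = integer(0),
                           orientation = character(0), register = integer(0))
  }
  if (nrow(pairings) > 0) {
    if (any(pairings$a == pairings$b)) stop("a strand cannot pair with itself")
    deg <- table(c(pairings$a, pairings$b))
    if (any(deg > 2)) stop("a strand can pair with at most 2 others")
    for (k in seq_len(nrow(pairings))) {
      seg <- aligned_segment(strands[pairings$a[k], ],
                             strands[pairings$b[k], ],
                             pairings$orientation[k], pairings$register[k])
      if (seg$k < 3L) stop("aligned overlap must span >= 3 residues")
    }
  }
  structure(list(length = length, strands = strands, pairings = pairings),
            class = "sheet_topology")
}

#' @export
print.sheet_topology <- function(x, ...) {
  cat(sprintf("Sheet topology: L = %d, %d strands, %d pairings\n",
              x$length, nrow(x$strands), nrow(x$pairings)))
  invisible(x)
}

# Aligned segment of a strand pairing: global start positions a, b of the
# aligned stretches and the overlap length k. Parallel: A position p
# pairs with B position p + r. Antiparallel: A position p pairs with B
# position r - p.
aligned_segment <- function(strand_a, strand_b, orientation, register) {
  la <- strand_a[2]; lb <- strand_b[2]; r <- register
  if (orientation == "parallel") {
    p0 <- max(0L, -r)
    p1 <- min(la - 1L, lb - 1L - r)
    k <- p1 - p0 + 1L
    list(a = strand_a[1] + p0, b = strand_b[1] + p0 + r, k = max(0L, k))
  } else {
    p0 <- max(0L, r - lb + 1L)
    p1 <- min(la - 1L, r)
    k <- p1 - p0 + 1L
    # B segment start corresponds to the *last* A position
    list(a = strand_a[1] + p0, b = strand_b[1] + r - p1, k = max(0L, k))
  }
}

#' Sample a random sheet topology
#'
#' Strand lengths are uniform on 3-10; strands are placed left to right
#' with at least two loop residues between them, with the remaining slack
#' distributed uniformly over the gaps. Pairings chain the strands in a
#' random order; orientations are uniform and registers are drawn
#' uniformly among those giving an aligned overlap of at least 3
#' residues. Draws from R's global random number stream.
#'
#' @param params A [simulation_params()].
#' @param max_tries Retries before giving up on an infeasible setting.
#' @return A [sheet_topology()].
#' @export
sample_topology <- function(params = simulation_params(), max_tries = 50L) {
  L <- if (params$length_range[1] == params$length_range[2]) {
    params$length_range[1]
  } else {
    sample(params$length_range[1]:params$length_range[2], 1L)
  }
  n_s <- if (params$n_strand_range[1] == params$n_strand_range[2]) {
    params$n_strand_range[1]
  } else {
    sample(params$n_strand_range[1]:params$n_strand_range[2], 1L)
  }
  if (n_s == 0L) return(sheet_topology(L, NULL, NULL))
  for (try in seq_len(max_tries)) {
    lens <- sample(3:10, n_s, replace = TRUE)
    slack <- L - sum(lens) - 2L * (n_s - 1L)
    if (slack < 0L) next
    # distribute slack over n_s + 1 gaps (termini included)
    extra <- if (slack > 0L) {
      tabulate(sample.int(n_s + 1L, slack, replace = TRUE), n_s + 1L)
    } else {
      integer(n_s + 1L)
    }
    starts <- integer(n_s)
    pos <- extra[1]
    for (s in seq_len(n_s)) {
      starts[s] <- pos
      pos <- pos + lens[s] + 2L + extra[s + 1L]
    }
    strands <- cbind(starts, lens)
    if (n_s < 2L) return(sheet_topology(L, strands, NULL))
    ord <- sample.int(n_s)
    pair_rows <- list()
    ok <- TRUE
    for (k in seq_len(n_s - 1L)) {
      a <- ord[k]; b <- ord[k + 1L]
      orientation <- sample(c("parallel", "antiparallel"), 1L)
      la <- lens[a]; lb <- lens[b]
      regs <- if (orientation == "parallel") {
        seq(-(la - 3L), lb - 3L)
      } else {
        # overlap >= 3 needs 2 <= r <= la + lb - 4
        seq(2L, la + lb - 4L)
      }
      regs <- Filter(function(r) {
        aligned_segment(c(0L, la), c(0L, lb), orientation, r)$k >= 3L
      }, regs)
      if (!length(regs)) { ok <- FALSE; break }
      pair_rows[[k]] <- data.frame(
        a = a, b = b, orientation = orientation,
        register = if (length(regs) == 1L) regs else sample(regs, 1L))
    }
    if (!ok) next
    return(sheet_topology(L, strands, do.call(rbind, pair_rows)))
  }
  stop("could not sample a feasible topology for these parameters")
}

#' Ground-truth labels of a topology
#'
#' For a parallel pairing whose aligned segments start at a and b with
#' overlap k, the pairs are `(a + m, b + m)`; for an antiparallel
#' pairing, `(a + m, b + k - 1 - m)`. Pairs at sequence separation below
#' 3 are dropped.
#'
#' @param topo A [sheet_topology()].
#' @return A [pairing_labels()].
#' @export
topology_to_labels <- function(topo) {
  stopifnot(inherits(topo, "sheet_topology"))
  rows <- list()
  for (p in seq_len(nrow(topo$pairings))) {
    pr <- topo$pairings[p, ]
    seg <- aligned_segment(topo$strands[pr$a, ], topo$strands[pr$b, ],
                           pr$orientation, pr$register)
    if (seg$k < 1L) next
    m <- seq_len(seg$k) - 1L
    j <- if (pr$orientation == "parallel") seg$b + m else seg$b + seg$k - 1L - m
    keep <- abs((seg$a + m) - j) >= MIN_SEPARATION
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- cbind(seg$a + m, j)[keep, , drop = FALSE]
    }
  }
  pairing_labels(topo$length, if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Simulate a noisy contact map from pairing labels
#'
#' The base map is 1 at every labelled pair and on the sequence-neighbor
#' band `|i - j| <= 2`. Each true pair is erased with probability
#' `miss_rate`, the map is Gaussian-blurred with `blur_sigma`, remaining
#' zero cells receive a uniform(0.3, 1) false positive with probability
#' `fp_density`, and values are clipped to \[0, 1\]. All corruption is
#' applied symmetrically, so the result is exactly symmetric. In the
#' noiseless limit (no misses, no blur, no false positives) thresholding
#' at 0.5 outside the neighbor band recovers the labels exactly.
#'
#' @param labels A [pairing_labels()].
#' @param L Protein length.
#' @param params A [simulation_params()].
#' @return A [contact_map()] with source `"synthetic"`.
#' @export
simulate_contact_map <- function(labels, L, params = simulation_params()) {
  stopifnot(inherits(labels, "pairing_labels"))
  m <- labels_matrix(labels)
  if (nrow(labels$pairs) > 0 && params$miss_rate > 0) {
    drop <- runif(nrow(labels$pairs)) < params$miss_rate
    if (any(drop)) {
      idx <- labels$pairs[drop, , drop = FALSE] + 1L
      m[idx] <- 0
      m[idx[, 2:1, drop = FALSE]] <- 0
    }
  }
  band <- !separation_mask(L)   # |i - j| <= 2 sequence-neighbor band
  m[band] <- 1
  if (params$blur_sigma > 0) {
    m <- gaussian_scale_space(m, params$blur_sigma^2)
  }
  if (params$fp_density > 0) {
    ut <- which(upper.tri(m) & m == 0)
    hit <- ut[runif(length(ut)) < params$fp_density]
    if (length(hit)) {
      vals <- runif(length(hit), 0.3, 1)
      m[hit] <- vals
      tm <- t(m)
      tm[hit] <- vals
      m <- t(tm)
    }
  }
  m <- pmin(pmax(m, 0), 1)
  m <- (m + t(m)) / 2
  contact_map(m, source = "synthetic")
}

#' Simulate a secondary-structure profile and sequence
#'
#' Strand residues get base probabilities (0.05, 0.9, 0.05) for
#' (helix, strand, coil) and all other residues (0.1, 0.05, 0.85). With
#' probability `ss_error_rate` a residue's strand/coil assignment is
#' flipped before jitter. Rows are then perturbed by Dirichlet jitter
#' centred on the base probabilities (concentration
#' `jitter_concentration`); with `jitter = FALSE` the base rows are
#' returned exactly. Sequence letters are uniform over the 20 canonical
#' residues and the alignment depth is log-uniform over
#' `n_homologs_range`.
#'
#' @param topo A [sheet_topology()].
#' @param params A [simulation_params()].
#' @param jitter Apply Dirichlet jitter to the rows.
#' @param jitter_concentration Dirichlet concentration (higher = less
#'   noise).
#' @return A [sequence_profile()].
#' @export
simulate_profile <- function(topo, params = simulation_params(),
                             jitter = TRUE, jitter_concentration = 60) {
  stopifnot(inherits(topo, "sheet_topology"))
  L <- topo$length
  in_strand <- rep(FALSE, L)
  for (s in seq_len(nrow(topo$strands))) {
    span <- topo$strands[s, 1] + seq_len(topo$strands[s, 2]) - 1L
    in_strand[span + 1L] <- TRUE
  }
  flip <- runif(L) < params$ss_error_rate
  eff <- xor(in_strand, flip)
  base_strand <- c(0.05, 0.90, 0.05)
  base_other <- c(0.10, 0.05, 0.85)
  ss3 <- t(vapply(eff, function(isb) if (isb) base_strand else base_other,
                  numeric(3)))
  if (jitter) {
    g <- matrix(rgamma(L * 3L, shape = ss3 * jitter_concentration, rate = 1),
                L, 3L)
    ss3 <- g / rowSums(g)
  }
  seq_ <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  lr <- log(params$n_homologs_range)
  n_hom <- exp(runif(1, lr[1], lr[2]))
  sequence_profile(seq_, ss3, n_homologs = n_hom)
}

#' Assemble the feature tensor of a simulated protein
#'
#' @param protein One element of a [generate_dataset()] result.
#' @param ridge A [ridge_params()] (only used if ridge maps are absent).
#' @param drop_groups Passed to [assemble_features()].
#' @return A [feature_tensor()].
#' @export
protein_features <- function(protein, ridge = ridge_params(),
                             drop_groups = NULL) {
  ra <- protein$ridge_a
  rb <- protein$ridge_b
  if (is.null(ra)) ra <- compute_ridge_features(protein$map_a, ridge)
  if (is.null(rb)) rb <- compute_ridge_features(protein$map_b, ridge)
  assemble_features(protein$map_a, protein$map_b, ra, rb,
                    protein$profile, drop_groups = drop_groups)
}

#' Generate a synthetic training/evaluation dataset
#'
#' Each protein carries a planted sheet topology, its ground-truth
#' pairing labels, two independently corrupted contact maps of the same
#' labels (emulating two upstream contact predictors with uncorrelated
#' errors), their ridge feature maps, and a simulated sequence profile.
#' Fully deterministic given `seed`.
#'
#' @param n Number of proteins (> 0).
#' @param params A [simulation_params()].
#' @param seed Integer seed.
#' @param ridge A [ridge_params()] used for the ridge maps.
#' @return List of protein bundles with elements `topology`, `labels`,
#'   `map_a`, `map_b`, `ridge_a`, `ridge_b`, `profile`, `id`.
#' @export
generate_dataset <- function(n, params = simulation_params(), seed = 1L,
                             ridge = ridge_params()) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    topo <- sample_topology(params)
    labels <- topology_to_labels(topo)
    map_a <- simulate_contact_map(labels, topo$length, params)
    map_b <- simulate_contact_map(labels, topo$length, params)
    profile <- simulate_profile(topo, params)
    list(id = sprintf("synthetic_%04d", k),
         topology = topo, labels = labels,
         map_a = map_a, map_b = map_b,
         ridge_a = compute_ridge_features(map_a, ridge),
         ridge_b = compute_ridge_features(map_b, ridge),
         profile = profile)
  })
}
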