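#' Broadcast per-residue features onto the pair grid
#'
#' Every column v of a per-residue feature matrix becomes two L x L
#' channels: a row-broadcast channel `R[i, j] = v[i]` and a
#' column-broadcast channel `C[i, j] = v[j]` (the transpose of the row
#' channel). Channels are interleaved per input column (row, then
#' column).
#'
#' @param profile_matrix L x k numeric matrix (k >= 1).
#' @return L x L x 2k numeric array.
#' @export
broadcast_1d <- function(profile_matrix) {
  m <- as.matrix(profile_matrix)
  if (ncol(m) < 1L || nrow(m) < 1L) stop("profile matrix must be nonempty")
  L <- nrow(m)
  out <- array(0, dim = c(L, L, 2L * ncol(m)))
  for (k in seq_len(ncol(m))) {
    rowc <- matrix(m[, k], L, L)          # R[i, j] = v[i]
    out[, , 2L * k - 1L] <- rowc
    out[, , 2L * k] <- t(rowc)            # C[i, j] = v[j]
  }
  out
}

# One-hot encoding of the sequence over the 20 canonical residues;
# non-canonical letters (X, B, Z, ...) get all-zero rows.
one_hot_sequence <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  m <- matrix(0, length(letters), length(AA_ALPHABET))
  colnames(m) <- AA_ALPHABET
  hit <- match(letters, AA_ALPHABET)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

# Fixed channel layout of the network input. Groups allow feature-removal
# experiments by dropping whole blocks of channels.
channel_registry <- function() {
  reg <- c(
    maps = list(c("ccm_map", "dcp_map")),
    ridge_height = list(c("ridge_height_a", "ridge_height_b")),
    ridge_direction = list(c("ridge_cos2_a", "ridge_sin2_a",
                             "ridge_cos2_b", "ridge_sin2_b")),
    ss3 = list(as.vector(t(outer(c("ss3_helix", "ss3_strand", "ss3_coil"),
                                 c("_row", "_col"), paste0)))),
    aa_onehot = list(as.vector(t(outer(paste0("aa_", AA_ALPHABET),
                                       c("_row", "_col"), paste0)))),
    global = list(c("log_homologs", "rel_length"))
  )
  reg
}

#' Feature tensor
#'
#' The channel-stacked L x L network input: 2D maps, broadcast 1D
#' profiles and constant 0D planes, together with a symmetric validity
#' mask that excludes pairs at sequence separation below 3.
#'
#' @param channels L x L x C numeric array.
#' @param registry Character vector of channel names (length C).
#' @param mask Symmetric logical L x L matrix.
#' @return An object of class `"feature_tensor"`.
#' @export
feature_tensor <- function(channels, registry, mask) {
  stopifnot(is.array(channels), length(dim(channels)) == 3L)
  L <- dim(channels)[1]
  if (dim(channels)[2] != L) stop("channels must be L x L x C")
  if (dim(channels)[3] != length(registry)) {
    stop("channel count (", dim(channels)[3], ") and registry length (",
         length(registry), ") disagree")
  }
  if (!all(is.finite(channels))) stop("feature tensor has non-finite values")
  if (!is.logical(mask) || !all(dim(mask) == c(L, L))) {
    stop("mask must be a logical L x L matrix")
  }
  if (!identical(mask, t(mask))) stop("mask must be symmetric")
  if (any(mask & !separation_mask(L))) {
    stop("mask must exclude pairs at separation < ", MIN_SEPARATION)
  }
  structure(list(length = L, channels = channels,
                 channel_registry = as.character(registry), mask = mask),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("Feature tensor: L = %d, %d channels, %d valid pairs\n",
              x$length, length(x$channel_registry), sum(x$mask) / 2))
  invisible(x)
}

#' Assemble the network input from maps, ridge features and the profile
#'
#' Stacks, in a fixed registry order: the two predicted contact maps
#' (coupling-score map first), the ridge height and direction channels of
#' both maps, row/column broadcasts of the 3-state secondary-structure
#' probabilities and of the one-hot amino-acid encoding, and two constant
#' planes `log(1 + N) / 10` (alignment depth) and `L / 500` (chain
#' length). The coupling-score map is divided by its own maximum when
#' that maximum exceeds 1, and both maps are clipped to \[0, 1\]; ridge
#' heights are normalized per map to \[0, 1\].
#'
#' @param map_a [contact_map()] holding the coupling-score source
#'   (CCMpred-like, unbounded above).
#' @param map_b [contact_map()] holding the probability-score source
#'   (DeepConPred2-like).
#' @param ridge_a,ridge_b [ridge_map()]s computed from `map_a` / `map_b`.
#' @param profile A [sequence_profile()].
#' @param drop_groups Character vector of channel groups to zero out
#'   (`"maps"`, `"ridge_height"`, `"ridge_direction"`, `"ss3"`,
#'   `"aa_onehot"`, `"global"`), for feature-removal experiments. The
#'   channel layout is unchanged.
#' @return A [feature_tensor()] with 56 channels.
#' @export
assemble_features <- function(map_a, map_b, ridge_a, ridge_b, profile,
                              drop_groups = NULL) {
  stopifnot(inherits(map_a, "contact_map"), inherits(map_b, "contact_map"),
            inherits(ridge_a, "ridge_map"), inherits(ridge_b, "ridge_map"),
            inherits(profile, "sequence_profile"))
  L <- map_a$length
  lens <- c(map_b$length, ridge_a$length, ridge_b$length, profile$length)
  if (any(lens != L)) {
    stop("input lengths disagree: ", paste(c(L, lens), collapse = ", "))
  }
  reg <- channel_registry()
  if (!is.null(drop_groups)) {
    unknown <- setdiff(drop_groups, names(reg))
    if (length(unknown)) stop("unknown channel group(s): ",
                              paste(unknown, collapse = ", "))
  }
  names_flat <- unlist(reg, use.names = FALSE)
  C <- length(names_flat)
  x <- array(0, dim = c(L, L, C))
  ch <- function(name) match(name, names_flat)

  norm_map <- function(v, rescale) {
    if (rescale && max(v) > 1) v <- v / max(v)
    pmin(pmax(v, 0), 1)
  }
  x[, , ch("ccm_map")] <- norm_map(map_a$values, rescale = TRUE)
  x[, , ch("dcp_map")] <- norm_map(map_b$values, rescale = FALSE)

  norm_height <- function(h) if (max(h) > 0) h / max(h) else h
  x[, , ch("ridge_height_a")] <- norm_height(ridge_a$height)
  x[, , ch("ridge_height_b")] <- norm_height(ridge_b$height)
  x[, , ch("ridge_cos2_a")] <- ridge_a$cos2
  x[, , ch("ridge_sin2_a")] <- ridge_a$sin2
  x[, , ch("ridge_cos2_b")] <- ridge_b$cos2
  x[, , ch("ridge_sin2_b")] <- ridge_b$sin2

  oned <- cbind(profile$ss3, one_hot_sequence(profile$sequence))
  bc <- broadcast_1d(oned)
  oned_names <- c(reg$ss3, reg$aa_onehot)
  for (k in seq_along(oned_names)) {
    x[, , ch(oned_names[k])] <- bc[, , k]
  }

  x[, , ch("log_homologs")] <- log1p(profile$n_homologs) / 10
  x[, , ch("rel_length")] <- L / 500

  if (!is.null(drop_groups)) {
    for (g in drop_groups) {
      for (name in reg[[g]]) x[, , ch(name)] <- 0
    }
  }
  feature_tensor(x, names_flat, separation_mask(L))
}

#' Pad a batch of feature tensors to a common size
#'
#' Zero-pads every tensor to the maximum length in the batch. The batch
#' mask marks real (non-padded, valid-separation) pairs, so padded
#' regions never contribute to normalization statistics or the loss.
#'
#' @param tensors Nonempty list of [feature_tensor()]s with identical
#'   channel registries.
#' @return List with `batch` (Lmax x Lmax x C x n array), `mask`
#'   (Lmax x Lmax x n logical array), `lengths`, and `registry`.
#' @export
pad_batch <- function(tensors) {
  if (!length(tensors)) stop("empty batch")
  regs <- lapply(tensors, `[[`, "channel_registry")
  if (!all(vapply(regs, identical, TRUE, y = regs[[1]]))) {
    stop("tensors in a batch must share a channel registry")
  }
  lens <- vapply(tensors, `[[`, 1L, "length")
  Lmax <- max(lens)
  C <- length(regs[[1]])
  n <- length(tensors)
  batch <- array(0, dim = c(Lmax, Lmax, C, n))
  mask <- array(FALSE, dim = c(Lmax, Lmax, n))
  for (b in seq_len(n)) {
    L <- lens[b]
    batch[seq_len(L), seq_len(L), , b] <- tensors[[b]]$channels
    mask[seq_len(L), seq_len(L), b] <- tensors[[b]]$mask
  }
  list(batch = batch, mask = mask, lengths = lens, registry = regs[[1]])
}

#' @rdname pad_batch
#' @param padded A batch produced by `pad_batch`.
#' @return `unpad_batch` returns the list of original [feature_tensor()]s.
#' @export
unpad_batch <- function(padded) {
  lapply(seq_along(padded$lengths), function(b) {
    L <- padded$lengths[b]
    ch <- padded$batch[seq_len(L), seq_len(L), , b, drop = FALSE]
    dim(ch) <- dim(ch)[1:3]
    feature_tensor(ch, padded$registry,
                   matrix(padded$mask[seq_len(L), seq_len(L), b], L, L))
  })
}
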