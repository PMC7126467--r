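#' Build a folding distance-constraint set
#'
#' Converts a beta-beta pairing probability map plus a general contact
#' map into at most L distance constraints for contact-guided folding.
#' Predicted beta pairs (probability >= `cutoff`) come first, ranked by
#' probability and constrained to a C-beta distance of 3.5-6 Angstrom
#' (high confidence); if fewer than L, the list is enriched with the
#' highest-ranked non-redundant pairs of the general contact map at
#' 3.5-10 Angstrom until the total reaches `min(L, available pairs)`.
#' Ordering is deterministic: ties break by smaller i, then smaller j.
#'
#' @param beta A [pairing_prob_map()].
#' @param general A [contact_map()] (general-purpose contact predictor).
#' @param cutoff Beta-pair decision threshold in \[0, 1\].
#' @return An object of class `"constraint_set"`: list with `length` and
#'   a data frame `entries` with columns `i`, `j` (0-based), `dmin`,
#'   `dmax`, `confidence`, `tag`.
#' @export
build_constraints <- function(beta, general, cutoff) {
  stopifnot(inherits(beta, "pairing_prob_map"),
            inherits(general, "contact_map"))
  if (beta$length != general$length) {
    stop("beta map (L = ", beta$length, ") and general map (L = ",
         general$length, ") disagree")
  }
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  L <- beta$length
  valid <- upper.tri(beta$probs) & separation_mask(L)
  idx <- which(valid, arr.ind = TRUE)
  bprob <- beta$probs[valid]
  gval <- general$values[valid]

  bsel <- which(bprob >= cutoff)
  bsel <- bsel[order(-bprob[bsel], idx[bsel, 1], idx[bsel, 2])]
  if (length(bsel) > L) bsel <- bsel[seq_len(L)]

  entries <- data.frame(
    i = idx[bsel, 1] - 1L, j = idx[bsel, 2] - 1L,
    dmin = rep(3.5, length(bsel)), dmax = rep(6.0, length(bsel)),
    confidence = pmin(pmax(bprob[bsel], 0), 1),
    tag = rep("beta", length(bsel)),
    stringsAsFactors = FALSE)

  gavail <- setdiff(which(gval > 0), bsel)
  n_fill <- min(L, length(bsel) + length(gavail)) - length(bsel)
  if (n_fill > 0) {
    gsel <- gavail[order(-gval[gavail], idx[gavail, 1], idx[gavail, 2])]
    gsel <- gsel[seq_len(n_fill)]
    entries <- rbind(entries, data.frame(
      i = idx[gsel, 1] - 1L, j = idx[gsel, 2] - 1L,
      dmin = 3.5, dmax = 10.0,
      confidence = pmin(pmax(gval[gsel], 0), 1), tag = "general",
      stringsAsFactors = FALSE))
  }
  rownames(entries) <- NULL
  structure(list(length = L, entries = entries), class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("Constraint set: L = %d, %d entries (%d beta, %d general)\n",
              x$length, nrow(x$entries), sum(x$entries$tag == "beta"),
              sum(x$entries$tag == "general")))
  invisible(x)
}

#' Write / read constraints in RR restraint format
#'
#' Lines `"i j dmin dmax confidence"` with 1-based indices, beta entries
#' first, preceded by a `PFRMAT RR` header. The round trip preserves
#' `(i, j, dmin, dmax)` exactly.
#'
#' @param cs A `"constraint_set"` from [build_constraints()].
#' @param path Output file.
#' @return `write_rr_constraints` returns `path` invisibly;
#'   `read_rr_constraints` returns a data frame with 0-based `i`, `j`,
#'   `dmin`, `dmax`, `confidence` and a `tag` inferred from the distance
#'   range.
#' @export
write_rr_constraints <- function(cs, path) {
  stopifnot(inherits(cs, "constraint_set"))
  e <- cs$entries
  lines <- c("PFRMAT RR",
             if (nrow(e) > 0)
               sprintf("%d %d %.1f %.1f %.6f", e$i + 1L, e$j + 1L,
                       e$dmin, e$dmax, e$confidence))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rr_constraints
#' @export
read_rr_constraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines)]
  rows <- list()
  for (k in seq_along(lines)) {
    toks <- .numeric_tokens(lines[k])
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals[1:2])) next   # header
    if (length(vals) < 5L || anyNA(vals[1:5])) {
      stop("malformed constraint record on line ", k, " of ", path)
    }
    rows[[length(rows) + 1L]] <- vals[1:5]
  }
  if (!length(rows)) {
    return(data.frame(i = integer(0), j = integer(0), dmin = numeric(0),
                      dmax = numeric(0), confidence = numeric(0),
                      tag = character(0)))
  }
  m <- do.call(rbind, rows)
  data.frame(i = as.integer(m[, 1]) - 1L, j = as.integer(m[, 2]) - 1L,
             dmin = m[, 3], dmax = m[, 4], confidence = m[, 5],
             tag = ifelse(m[, 4] <= 6, "beta", "general"),
             stringsAsFactors = FALSE)
}
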