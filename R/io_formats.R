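#' @useDynLib betapair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma predict coef
#' @importFrom utils head read.table write.table
NULL

# Canonical amino-acid alphabet used for one-hot encoding.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Minimum sequence separation for a cross-strand pair: the tightest
# beta hairpin bridges residue i with i+3, so closer pairs are excluded
# from masks, labels and predictions throughout.
MIN_SEPARATION <- 3L

#' Validity mask for residue pairs
#'
#' Logical L x L matrix that is `TRUE` for pairs at sequence separation
#' `|i - j| >= min_sep`. Pairs closer in sequence cannot be hydrogen-bonded
#' partners in distinct strands.
#'
#' @param length Protein length L.
#' @param min_sep Minimum separation (default 3).
#' @return Symmetric logical matrix.
#' @export
separation_mask <- function(length, min_sep = MIN_SEPARATION) {
  idx <- seq_len(length)
  abs(outer(idx, idx, "-")) >= min_sep
}

#' Contact map
#'
#' A symmetric L x L matrix of predicted residue-residue contact strength.
#' Contacts are conventionally defined by a C-beta/C-beta distance below
#' 8 Angstrom; the values here are whatever score the upstream predictor
#' emits (coupling strengths are unbounded above, probabilities lie in
#' \[0, 1\]). Asymmetric input is symmetrized by averaging with its
#' transpose.
#'
#' @param values Square numeric matrix.
#' @param source Free-text tag recording the score's origin, e.g.
#'   `"ccmpred"`, `"deepconpred2"` or `"synthetic"`.
#' @return An object of class `"contact_map"` with fields `length`,
#'   `values` and `source`.
#' @export
contact_map <- function(values, source = "unknown") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("contact map must be square, got ", nrow(values), " x ", ncol(values))
  }
  if (nrow(values) < 1L) stop("contact map must have L >= 1")
  if (!all(is.finite(values))) stop("contact map contains non-finite values")
  values <- (values + t(values)) / 2
  dimnames(values) <- NULL
  structure(list(length = nrow(values), values = values, source = source),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: L = %d, source = %s, value range [%.4g, %.4g]\n",
              x$length, x$source, min(x$values), max(x$values)))
  invisible(x)
}

#' Sequence profile
#'
#' Per-residue sequence-level information: the amino-acid sequence, a
#' 3-state secondary-structure probability profile (helix, strand, coil),
#' and the number of homologous sequences in the alignment the contact
#' maps were computed from.
#'
#' @param sequence Amino-acid string of length L.
#' @param ss3 L x 3 matrix of (helix, strand, coil) probabilities; every
#'   row must sum to 1 within 1e-3.
#' @param n_homologs Nonnegative scalar, the alignment depth N.
#' @return An object of class `"sequence_profile"`.
#' @export
sequence_profile <- function(sequence, ss3, n_homologs = 0) {
  sequence <- toupper(as.character(sequence)[1])
  ss3 <- as.matrix(ss3)
  if (ncol(ss3) != 3L) stop("ss3 must have exactly 3 columns")
  L <- nchar(sequence)
  if (nrow(ss3) != L) {
    stop("sequence length (", L, ") and ss3 row count (", nrow(ss3),
         ") disagree")
  }
  if (!all(is.finite(ss3)) || any(ss3 < 0)) {
    stop("ss3 probabilities must be finite and nonnegative")
  }
  bad <- abs(rowSums(ss3) - 1) > 1e-3
  if (any(bad)) {
    stop("ss3 row(s) ", paste(which(bad)[1:min(3, sum(bad))], collapse = ", "),
         " do not sum to 1 within 1e-3")
  }
  if (length(n_homologs) != 1L || !is.finite(n_homologs) || n_homologs < 0) {
    stop("n_homologs must be a single nonnegative number")
  }
  dimnames(ss3) <- list(NULL, c("helix", "strand", "coil"))
  structure(list(sequence = sequence, ss3 = ss3,
                 n_homologs = as.numeric(n_homologs), length = L),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("Sequence profile: L = %d, N = %.1f homologs\n",
              x$length, x$n_homologs))
  invisible(x)
}

#' Ground-truth beta-beta pairing labels
#'
#' The set of unordered residue pairs that form backbone hydrogen bonds
#' between beta strands (bridge partners). Indices are 0-based internally;
#' all pairs satisfy `|i - j| >= 3`.
#'
#' @param length Protein length L.
#' @param pairs Two-column matrix of 0-based residue indices (unordered
#'   pairs; duplicates are collapsed).
#' @return An object of class `"pairing_labels"` with a canonical
#'   `pairs` matrix (i < j, sorted).
#' @export
pairing_labels <- function(length, pairs) {
  length <- as.integer(length)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
  }
  if (nrow(pairs) > 0) {
    if (any(pairs < 0L) || any(pairs >= length)) {
      stop("pair indices must lie in [0, L)")
    }
    i <- pmin(pairs[, 1], pairs[, 2])
    j <- pmax(pairs[, 1], pairs[, 2])
    if (any(j - i < MIN_SEPARATION)) {
      stop("pairs at sequence separation < ", MIN_SEPARATION,
           " cannot be cross-strand partners")
    }
    pairs <- unique(cbind(i, j))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(list(length = length, pairs = pairs), class = "pairing_labels")
}

#' @export
print.pairing_labels <- function(x, ...) {
  cat(sprintf("Pairing labels: L = %d, %d hydrogen-bonded pairs\n",
              x$length, nrow(x$pairs)))
  invisible(x)
}

#' Dense 0/1 matrix view of pairing labels
#'
#' @param labels A `pairing_labels` object.
#' @return Symmetric L x L numeric matrix with 1 at labelled pairs.
#' @export
labels_matrix <- function(labels) {
  m <- matrix(0, labels$length, labels$length)
  if (nrow(labels$pairs) > 0) {
    idx <- labels$pairs + 1L
    m[idx] <- 1
    m[idx[, 2:1, drop = FALSE]] <- 1
  }
  m
}

#' Pairing probability map
#'
#' Symmetric L x L matrix of predicted probabilities that each residue
#' pair forms a hydrogen-bonded beta-beta interaction. Entries at
#' sequence separation below 3 are exactly zero.
#'
#' @param probs Square numeric matrix with entries in \[0, 1\], symmetric
#'   within 1e-8.
#' @return An object of class `"pairing_prob_map"`.
#' @export
pairing_prob_map <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) stop("probability map must be square")
  if (!all(is.finite(probs))) stop("probability map contains non-finite values")
  if (any(probs < 0) || any(probs > 1)) {
    stop("probability map entries must lie in [0, 1]")
  }
  if (max(abs(probs - t(probs))) > 1e-8) {
    stop("probability map is not symmetric")
  }
  probs <- (probs + t(probs)) / 2
  probs[!separation_mask(nrow(probs))] <- 0
  dimnames(probs) <- NULL
  structure(list(length = nrow(probs), probs = probs),
            class = "pairing_prob_map")
}

#' @export
print.pairing_prob_map <- function(x, ...) {
  cat(sprintf("Pairing probability map: L = %d, max prob %.4f\n",
              x$length, max(x$probs)))
  invisible(x)
}

.numeric_tokens <- function(line) {
  strsplit(trimws(line), "[ \t]+")[[1]]
}

#' Read a predicted contact map
#'
#' Reads either a CCMpred-style dense matrix (L whitespace-separated rows
#' of L numbers) or a CASP RR contact list (optional header lines, then
#' `"i j dmin dmax prob"` records with 1-based indices). RR cells not
#' listed default to 0. The result is symmetrized as `(M + t(M)) / 2`.
#'
#' @param path File to read.
#' @param format `"matrix"` or `"rr"`.
#' @param length Protein length, required for the `"rr"` dialect.
#' @param source Source tag stored on the returned map.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, format = c("matrix", "rr"),
                             length = NULL, source = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (is.null(source)) source <- format
  if (format == "matrix") {
    keep <- which(nzchar(trimws(lines)))
    if (length(keep) == 0L) stop("empty contact matrix file: ", path)
    rows <- lapply(keep, function(k) {
      toks <- .numeric_tokens(lines[k])
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals)) {
        stop("non-numeric token on line ", k, " of ", path)
      }
      vals
    })
    n <- vapply(rows, length, 1L)
    if (any(n != n[1]) || n[1] != length(rows)) {
      bad <- keep[which(n != n[1])[1]]
      if (is.na(bad)) bad <- keep[length(keep)]
      stop("ragged or non-square matrix near line ", bad, " of ", path)
    }
    m <- do.call(rbind, rows)
    return(contact_map(m, source = source))
  }
  # RR dialect
  if (is.null(length)) stop("length is required for the RR dialect")
  L <- as.integer(length)
  m <- matrix(0, L, L)
  in_data <- FALSE
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line)) next
    toks <- .numeric_tokens(line)
    first <- suppressWarnings(as.integer(toks[1]))
    if (!in_data && is.na(first)) next   # header line
    in_data <- TRUE
    if (toupper(toks[1]) == "END") break
    vals <- suppressWarnings(as.numeric(toks))
    if (length(toks) < 5L || anyNA(vals[1:5])) {
      stop("malformed RR record on line ", k, " of ", path)
    }
    i <- as.integer(vals[1]); j <- as.integer(vals[2])
    if (i < 1L || i > L || j < 1L || j > L) {
      stop("RR residue index out of [1, ", L, "] on line ", k, " of ", path)
    }
    m[i, j] <- vals[5]
    m[j, i] <- vals[5]
  }
  contact_map(m, source = source)
}

#' Read a sequence profile from FASTA and SS3 files
#'
#' The FASTA file must hold exactly one record. The SS3 file has one row
#' per residue whose three final numeric columns are taken as the
#' (helix, strand, coil) probabilities; lines starting with `#` are
#' ignored. Rows are renormalized to sum to 1 when they are within 1e-2
#' of 1, and rejected otherwise.
#'
#' @param fasta_path Path to the FASTA file.
#' @param ss3_path Path to the secondary-structure probability file.
#' @param n_homologs Alignment depth N (a given scalar).
#' @return A [sequence_profile()].
#' @export
read_sequence_profile <- function(fasta_path, ss3_path, n_homologs = 0) {
  fa <- read_fasta_single(fasta_path)
  lines <- readLines(ss3_path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  ss3 <- matrix(NA_real_, length(lines), 3)
  for (k in seq_along(lines)) {
    toks <- .numeric_tokens(lines[k])
    vals <- suppressWarnings(as.numeric(toks))
    num <- vals[!is.na(vals)]
    if (length(num) < 3L) stop("fewer than 3 numeric columns in SS3 row ", k)
    ss3[k, ] <- utils::tail(num, 3)
  }
  if (nrow(ss3) != nchar(fa)) {
    stop("FASTA length (", nchar(fa), ") and SS3 row count (", nrow(ss3),
         ") disagree")
  }
  s <- rowSums(ss3)
  bad <- abs(s - 1) > 1e-2
  if (any(bad)) {
    stop("SS3 row ", which(bad)[1], " sums to ", signif(s[which(bad)[1]], 4),
         "; not renormalizable")
  }
  ss3 <- ss3 / s
  sequence_profile(fa, ss3, n_homologs = n_homologs)
}

# Single-record FASTA reader (the only FASTA shape the pipeline accepts).
read_fasta_single <- function(path) {
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       seqonly = TRUE),
    error = function(e) stop("no FASTA record in ", path, ": ",
                             conditionMessage(e)))
  if (length(recs) != 1L) {
    stop("FASTA file must hold exactly one record, found ", length(recs))
  }
  seq <- gsub("\\s", "", toupper(recs[[1]]))
  if (!nzchar(seq)) stop("empty FASTA sequence in ", path)
  seq
}

#' Extract beta-bridge partners from DSSP output
#'
#' Parses the residue table of classic `dssp` output and collects, for
#' every residue assigned extended strand (`E`) or isolated beta bridge
#' (`B`), its nonzero bridge partners from the fixed-column BP1/BP2
#' fields. Partner indices use DSSP's sequential residue numbering (the
#' `#` column), converted to 0-based; chain-break placeholders (`!`) are
#' skipped. Self-pairs and pairs at sequence separation below 3 are
#' rejected with a warning.
#'
#' @param dssp Either a path to a DSSP file or the DSSP text itself
#'   (single string or character vector of lines).
#' @return A [pairing_labels()].
#' @export
parse_dssp_bridge_partners <- function(dssp) {
  if (length(dssp) == 1L && !grepl("\n", dssp) && file.exists(dssp)) {
    lines <- readLines(dssp, warn = FALSE)
  } else {
    lines <- unlist(strsplit(dssp, "\n", fixed = TRUE))
  }
  lines <- sub("\r$", "", lines)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0L) {
    stop("not a DSSP file: residue table header ('#  RESIDUE ...') not found")
  }
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  n_res <- 0L
  pairs <- list()
  rejected <- 0L
  for (line in body) {
    num <- suppressWarnings(as.integer(substr(line, 1, 5)))
    if (is.na(num)) next
    n_res <- max(n_res, num)
    aa <- substr(line, 14, 14)
    if (aa == "!") next                      # chain break placeholder
    ss <- substr(line, 17, 17)
    if (!ss %in% c("E", "B")) next
    for (bp_col in list(c(26, 29), c(30, 33))) {
      bp <- suppressWarnings(as.integer(substr(line, bp_col[1], bp_col[2])))
      if (is.na(bp) || bp == 0L) next
      i <- num - 1L
      j <- bp - 1L
      if (i == j || abs(i - j) < MIN_SEPARATION) {
        rejected <- rejected + 1L
        next
      }
      pairs[[length(pairs) + 1L]] <- c(min(i, j), max(i, j))
    }
  }
  if (rejected > 0L) {
    warning(rejected, " bridge-partner record(s) rejected ",
            "(self-pairing or separation < ", MIN_SEPARATION, ")")
  }
  if (n_res == 0L) stop("DSSP residue table is empty")
  pm <- if (length(pairs)) do.call(rbind, pairs) else NULL
  pairing_labels(n_res, pm)
}

#' Write / read a pairing probability matrix
#'
#' Plain-text L x L matrix with 6 decimal places. `read_probability_matrix`
#' validates symmetry and the \[0, 1\] range and errors otherwise; the
#' round trip reproduces entries within 1e-6.
#'
#' @param pmap A [pairing_prob_map()].
#' @param path File path.
#' @return `write_probability_matrix` returns `path` invisibly;
#'   `read_probability_matrix` returns a [pairing_prob_map()].
#' @export
write_probability_matrix <- function(pmap, path) {
  stopifnot(inherits(pmap, "pairing_prob_map"))
  txt <- apply(pmap$probs, 1, function(r) paste(sprintf("%.6f", r),
                                                collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_probability_matrix
#' @export
read_probability_matrix <- function(path) {
  m <- read_contact_map(path, format = "matrix")$values
  if (any(m < 0) || any(m > 1)) {
    stop("probability matrix in ", path, " has entries outside [0, 1]")
  }
  pairing_prob_map(m)
}

#' Write / read pairing labels as an RR-style pair list
#'
#' One line per pair, `"i j 0 8 1.0"` with 1-based indices, so label
#' files flow through the same RR machinery as contact lists.
#'
#' @param labels A [pairing_labels()].
#' @param path File path.
#' @param length Protein length (read side).
#' @return The labels (read side) or `path` invisibly (write side).
#' @export
write_pairing_labels <- function(labels, path) {
  stopifnot(inherits(labels, "pairing_labels"))
  lines <- c("PFRMAT RR",
             if (nrow(labels$pairs) > 0)
               sprintf("%d %d 0 8 1.000000",
                       labels$pairs[, 1] + 1L, labels$pairs[, 2] + 1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pairing_labels
#' @export
read_pairing_labels <- function(path, length) {
  cm <- read_contact_map(path, format = "rr", length = length)
  idx <- which(cm$values > 0 & upper.tri(cm$values), arr.ind = TRUE)
  pairing_labels(length, idx - 1L)
}
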