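#' Network architecture configuration
#'
#' Hyper-parameters of the residual network. The full-scale model uses 15
#' blocks and 45 channels with row/column normalization enabled; smaller
#' settings train in minutes on synthetic data. Each block applies two
#' repeats of (normalization, leaky ReLU, 3x3 convolution) around a
#' shortcut connection: the first repeat normalizes with the average of
#' row and column normalization (when `use_rncn`) or instance
#' normalization, the second always with instance normalization.
#'
#' @param n_blocks Number of residual blocks (>= 1).
#' @param n_channels Width of the trunk (>= 1).
#' @param use_rncn Use row/column normalization in the first repeat.
#' @param leaky_slope Negative-side slope of the leaky ReLU.
#' @param epsilon Stabilizer added to the standard deviation in every
#'   normalization.
#' @return An object of class `"pairnet_config"`.
#' @export
pairnet_config <- function(n_blocks = 15L, n_channels = 45L,
                           use_rncn = TRUE, leaky_slope = 0.01,
                           epsilon = 1e-5) {
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  if (n_channels < 1L) stop("n_channels must be >= 1")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (leaky_slope < 0 || leaky_slope >= 1) {
    stop("leaky_slope must lie in [0, 1)")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 n_channels = as.integer(n_channels),
                 use_rncn = isTRUE(use_rncn),
                 leaky_slope = leaky_slope, epsilon = epsilon),
            class = "pairnet_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (the full-scale protocol uses
#'   1e-4; small models on easy synthetic tasks tolerate larger rates).
#' @param n_folds Number of cross-validation folds (>= 2). The final
#'   predictor averages the fold models.
#' @param max_epochs Maximum passes over the training fold.
#' @param patience Early-stopping patience, in epochs without improvement
#'   of the validation F1 at its running optimal cutoff.
#' @param seed Master seed driving fold assignment, weight initialization
#'   and batch order.
#' @param positive_weight Loss weight on the positive (paired) class.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"train_control"`.
#' @export
train_control <- function(learning_rate = 1e-4, n_folds = 5L,
                          max_epochs = 30L, patience = 5L, seed = 1L,
                          positive_weight = 1, verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (n_folds < 2L) stop("n_folds must be >= 2 (got ", n_folds, ")")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  if (positive_weight <= 0) stop("positive_weight must be > 0")
  structure(list(learning_rate = learning_rate,
                 n_folds = as.integer(n_folds),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 positive_weight = positive_weight,
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

# config list handed to the C++ kernels
cpp_cfg <- function(config, n_input) {
  list(n_input = as.integer(n_input),
       n_channels = config$n_channels,
       n_blocks = config$n_blocks,
       use_rncn = config$use_rncn,
       leaky_slope = config$leaky_slope,
       epsilon = config$epsilon)
}

# Flat parameter layout; must mirror ParamView in src/pairnet.cpp.
# Offsets are 0-based.
pairnet_layout <- function(n_input, n_channels, n_blocks) {
  C <- n_channels
  conv_sz <- 9L * C * C
  block_sz <- 2L * conv_sz + 6L * C
  off_bin <- n_input * C
  off_blocks <- off_bin + C
  total <- off_blocks + n_blocks * block_sz + C + 1L
  list(Cin = n_input, C = C, B = n_blocks, conv_sz = conv_sz,
       block_sz = block_sz, off_bin = off_bin, off_blocks = off_blocks,
       off_wout = off_blocks + n_blocks * block_sz, total = total,
       # offsets inside a block
       b_g1 = 0L, b_be1 = C, b_W1 = 2L * C, b_b1 = 2L * C + conv_sz,
       b_g2 = 3L * C + conv_sz, b_be2 = 4L * C + conv_sz,
       b_W2 = 5L * C + conv_sz, b_b2 = 5L * C + 2L * conv_sz)
}

# 180-degree rotation symmetrization of a 3x3xCxC conv weight array.
# Tied kernels make the forward pass exactly equivariant under reversing
# the residue order (a 180-degree flip of every 2D channel).
symmetrize_conv <- function(w) {
  (w + w[3:1, 3:1, , , drop = FALSE]) / 2
}

conv_indices <- function(layout, block, which_conv) {
  base <- layout$off_blocks + (block - 1L) * layout$block_sz +
    if (which_conv == 1L) layout$b_W1 else layout$b_W2
  base + seq_len(layout$conv_sz)
}

# symmetrize the conv-weight sections of a flat parameter or gradient
# vector in place
symmetrize_conv_params <- function(v, layout) {
  C <- layout$C
  for (b in seq_len(layout$B)) {
    for (k in 1:2) {
      idx <- conv_indices(layout, b, k)
      w <- array(v[idx], dim = c(3, 3, C, C))
      v[idx] <- symmetrize_conv(w)
    }
  }
  v
}

#' Initialize network parameters
#'
#' He-style Gaussian initialization for the embedding and first in-block
#' convolutions; the second convolution of every block starts at zero so
#' each block begins as the identity map. 3x3 kernels are
#' 180-degree-rotation symmetric, which makes predictions invariant to
#' reversing the residue order.
#'
#' @param config A [pairnet_config()].
#' @param n_input Number of input channels.
#' @param seed Integer seed.
#' @return Numeric parameter vector.
#' @export
pairnet_init <- function(config, n_input, seed = 1L) {
  lay <- pairnet_layout(n_input, config$n_channels, config$n_blocks)
  C <- lay$C
  set.seed(seed)
  v <- numeric(lay$total)
  v[seq_len(n_input * C)] <- rnorm(n_input * C, 0, sqrt(2 / n_input))
  # bin = 0
  for (b in seq_len(lay$B)) {
    base <- lay$off_blocks + (b - 1L) * lay$block_sz
    v[base + lay$b_g1 + seq_len(C)] <- 1
    v[base + lay$b_g2 + seq_len(C)] <- 1
    w1 <- array(rnorm(lay$conv_sz, 0, sqrt(2 / (9 * C))), c(3, 3, C, C))
    v[base + lay$b_W1 + seq_len(lay$conv_sz)] <- symmetrize_conv(w1)
    # W2 stays 0: blocks start as identities
  }
  v[lay$off_wout + seq_len(C)] <- rnorm(C, 0, sqrt(1 / C))
  # bout = 0
  v
}

.norm_op <- function(x, mask, epsilon, gain, bias, axis) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == dim(x)[2])
  C <- dim(x)[3]
  if (is.null(gain)) gain <- rep(1, C)
  if (is.null(bias)) bias <- rep(0, C)
  if (is.null(mask)) mask <- matrix(TRUE, dim(x)[1], dim(x)[2])
  norm_forward_cpp(x, mask, epsilon, axis, as.numeric(gain),
                   as.numeric(bias))
}

#' Masked feature-map normalizations
#'
#' Standardize an L x L x C feature array using statistics computed over
#' masked-in entries only: per row and channel (`row_normalize`), per
#' column and channel (`column_normalize`), or per channel over all
#' masked pixels (`instance_normalize`). Every entry of a group is
#' standardized with the masked mean and standard deviation; groups with
#' fewer than 2 masked entries pass through unchanged. A per-channel
#' learnable gain and bias (defaults 1 and 0) follows.
#'
#' @param x L x L x C array (a matrix is treated as one channel).
#' @param mask Logical L x L validity matrix (`NULL` = all valid).
#' @param epsilon Added to the standard deviation before dividing.
#' @param gain,bias Per-channel affine parameters.
#' @return Array of the same shape.
#' @export
row_normalize <- function(x, mask = NULL, epsilon = 1e-5, gain = NULL,
                          bias = NULL) {
  .norm_op(x, mask, epsilon, gain, bias, axis = 0L)
}

#' @rdname row_normalize
#' @export
column_normalize <- function(x, mask = NULL, epsilon = 1e-5, gain = NULL,
                             bias = NULL) {
  .norm_op(x, mask, epsilon, gain, bias, axis = 1L)
}

#' @rdname row_normalize
#' @export
instance_normalize <- function(x, mask = NULL, epsilon = 1e-5, gain = NULL,
                               bias = NULL) {
  .norm_op(x, mask, epsilon, gain, bias, axis = 2L)
}

#' Apply one residual block
#'
#' `y = x + Conv3x3(LReLU(IN(Conv3x3(LReLU(N1(x))))))` where `N1` is the
#' average of row and column normalization when `use_rncn`, otherwise
#' instance normalization. Convolutions are zero-padded so the shape is
#' preserved; with all-zero convolution weights the block is exactly the
#' identity.
#'
#' @param x L x L x C array with `C == config$n_channels`.
#' @param params Named list with elements `g1`, `be1`, `W1` (3x3xCxC),
#'   `b1`, `g2`, `be2`, `W2`, `b2`.
#' @param mask Logical validity matrix (`NULL` = all valid).
#' @param config A [pairnet_config()].
#' @return Array of the same shape as `x`.
#' @export
resnet_block <- function(x, params, mask = NULL, config = pairnet_config()) {
  stopifnot(length(dim(x)) == 3L)
  C <- config$n_channels
  if (dim(x)[3] != C) {
    stop("input has ", dim(x)[3], " channels, block expects ", C)
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(x)[1], dim(x)[2])
  flat <- c(params$g1, params$be1, as.numeric(params$W1), params$b1,
            params$g2, params$be2, as.numeric(params$W2), params$b2)
  lay <- pairnet_layout(1L, C, 1L)
  if (length(flat) != lay$block_sz) {
    stop("block parameter list has wrong total size")
  }
  resnet_block_cpp(x, flat, mask, cpp_cfg(config, 1L))
}

#' Zero-initialized residual block parameters
#'
#' @param config A [pairnet_config()].
#' @return Named list accepted by [resnet_block()], with unit gains,
#'   zero biases and all-zero convolution weights.
#' @export
resnet_block_params <- function(config = pairnet_config()) {
  C <- config$n_channels
  list(g1 = rep(1, C), be1 = rep(0, C),
       W1 = array(0, c(3, 3, C, C)), b1 = rep(0, C),
       g2 = rep(1, C), be2 = rep(0, C),
       W2 = array(0, c(3, 3, C, C)), b2 = rep(0, C))
}

#' Single-model forward pass
#'
#' Embeds the feature tensor with a 1x1 convolution, applies the residual
#' blocks, maps to one channel, squashes with the logistic function,
#' symmetrizes as `(P + t(P)) / 2` and zeroes all pairs outside the
#' validity mask.
#'
#' @param params Flat parameter vector from [pairnet_init()].
#' @param features A [feature_tensor()].
#' @param config A [pairnet_config()].
#' @return A [pairing_prob_map()].
#' @export
pairnet_forward <- function(params, features, config = pairnet_config()) {
  stopifnot(inherits(features, "feature_tensor"))
  n_input <- dim(features$channels)[3]
  probs <- pairnet_forward_cpp(params, features$channels, features$mask,
                               cpp_cfg(config, n_input))
  pairing_prob_map(probs)
}

# one protein's (features, labels) pair from either a prepared pair or a
# simulated protein bundle
.training_example <- function(pr) {
  if (!is.null(pr$features) && inherits(pr$features, "feature_tensor")) {
    feats <- pr$features
  } else if (!is.null(pr$map_a)) {
    feats <- protein_features(pr)
  } else {
    stop("each training example needs a $features tensor or raw maps")
  }
  if (is.null(pr$labels) || !inherits(pr$labels, "pairing_labels")) {
    stop("each training example needs $labels (pairing_labels)")
  }
  if (feats$length != pr$labels$length) {
    stop("feature tensor and labels disagree on length")
  }
  list(features = feats, labels = pr$labels)
}

#' Fit the pairing network by k-fold cross-validation
#'
#' Splits proteins into `control$n_folds` folds under the master seed and
#' trains one model per fold on the remaining folds, minimizing masked
#' binary cross-entropy with Adam (one protein per step). After each
#' epoch the held-out fold is scored and the F1 at the running optimal
#' cutoff drives early stopping; the best-epoch weights are kept. The
#' returned predictor is the ensemble of fold models; its operating
#' cutoff is selected by maximizing pooled F1 over all out-of-fold
#' predictions.
#'
#' @param proteins List of training examples; each element either holds a
#'   `$features` [feature_tensor()] and `$labels` [pairing_labels()], or
#'   is a simulated protein bundle from [generate_dataset()].
#' @param config A [pairnet_config()].
#' @param control A [train_control()].
#' @return An object of class `"pairnet"` with fold parameter vectors,
#'   the selected cutoff and per-epoch history.
#' @export
fit_pairnet <- function(proteins, config = pairnet_config(),
                        control = train_control()) {
  stopifnot(inherits(config, "pairnet_config"),
            inherits(control, "train_control"))
  if (!length(proteins)) stop("empty training set")
  exs <- lapply(proteins, .training_example)
  n <- length(exs)
  if (control$n_folds > n) stop("more folds than proteins")
  xs <- lapply(exs, function(e) e$features$channels)
  masks <- lapply(exs, function(e) e$features$mask)
  ys <- lapply(exs, function(e) labels_matrix(e$labels))
  n_pos <- vapply(exs, function(e) nrow(e$labels$pairs), 1L)
  n_input <- dim(xs[[1]])[3]
  ccfg <- cpp_cfg(config, n_input)
  lay <- pairnet_layout(n_input, config$n_channels, config$n_blocks)

  set.seed(control$seed)
  fold_of <- sample(rep_len(seq_len(control$n_folds), n))

  fold_models <- vector("list", control$n_folds)
  fold_used <- logical(control$n_folds)
  history <- list()
  oof_preds <- vector("list", n)

  for (f in seq_len(control$n_folds)) {
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    if (sum(n_pos[tr]) == 0L || sum(n_pos[va]) == 0L) {
      warning("fold ", f, " has no positive pairs in train or validation; ",
              "skipping")
      next
    }
    params <- pairnet_init(config, n_input, seed = control$seed + f)
    mstate <- numeric(lay$total)
    vstate <- numeric(lay$total)
    step <- 0L
    best_f1 <- -Inf
    best_params <- params
    best_cut <- 0.5
    wait <- 0L
    set.seed(control$seed * 1000L + f)
    for (epoch in seq_len(control$max_epochs)) {
      losses <- numeric(0)
      for (idx in sample(tr)) {
        lg <- pairnet_loss_grad_cpp(params, xs[[idx]], masks[[idx]],
                                    ys[[idx]], ccfg,
                                    control$positive_weight)
        g <- symmetrize_conv_params(lg$grad, lay)
        step <- step + 1L
        mstate <- 0.9 * mstate + 0.1 * g
        vstate <- 0.999 * vstate + 0.001 * g * g
        mhat <- mstate / (1 - 0.9^step)
        vhat <- vstate / (1 - 0.999^step)
        params <- params - control$learning_rate * mhat /
          (sqrt(vhat) + 1e-8)
        losses <- c(losses, lg$loss)
      }
      val_preds <- lapply(va, function(idx) {
        pairnet_forward_cpp(params, xs[[idx]], masks[[idx]], ccfg)
      })
      truths <- lapply(va, function(idx) exs[[idx]]$labels)
      cut <- select_cutoff(val_preds, truths)
      cc <- Reduce(`+`, Map(function(p, tr_) {
        unlist(confusion_counts(p, tr_, cut))
      }, val_preds, truths))
      f1 <- precision_recall_f1(list(TP = cc[1], FP = cc[2], FN = cc[3]))[3]
      history[[length(history) + 1L]] <-
        data.frame(fold = f, epoch = epoch, train_loss = mean(losses),
                   val_f1 = as.numeric(f1), cutoff = cut)
      if (control$verbose) {
        message(sprintf("fold %d epoch %d: loss %.4f val F1 %.4f (cut %.3f)",
                        f, epoch, mean(losses), f1, cut))
      }
      if (f1 > best_f1 + 1e-12) {
        best_f1 <- f1
        best_params <- params
        best_cut <- cut
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    }
    fold_models[[f]] <- best_params
    fold_used[f] <- TRUE
    for (idx in va) {
      oof_preds[[idx]] <- pairnet_forward_cpp(best_params, xs[[idx]],
                                              masks[[idx]], ccfg)
    }
  }
  if (!any(fold_used)) stop("all folds degenerate; nothing was trained")
  keep <- which(!vapply(oof_preds, is.null, TRUE))
  cutoff <- select_cutoff(oof_preds[keep],
                          lapply(exs[keep], `[[`, "labels"))
  structure(list(fold_params = fold_models[fold_used],
                 fold_ids = which(fold_used),
                 config = config, control = control,
                 n_input = n_input, cutoff = cutoff,
                 fold_of = fold_of,
                 history = do.call(rbind, history),
                 registry = exs[[1]]$features$channel_registry),
            class = "pairnet")
}

#' Predict pairing probabilities with a fitted ensemble
#'
#' Arithmetic mean of the per-fold forward passes.
#'
#' @param object A fitted `"pairnet"`.
#' @param newdata A [feature_tensor()], a simulated protein bundle, or a
#'   list of either.
#' @param ... Unused.
#' @return A [pairing_prob_map()] (or a list of them).
#' @export
predict.pairnet <- function(object, newdata, ...) {
  one <- function(ft) {
    if (!inherits(ft, "feature_tensor")) {
      if (!is.null(ft$features)) ft <- ft$features
      else if (!is.null(ft$map_a)) ft <- protein_features(ft)
      else stop("newdata must contain feature tensors")
    }
    if (dim(ft$channels)[3] != object$n_input) {
      stop("feature tensor has ", dim(ft$channels)[3],
           " channels, model expects ", object$n_input)
    }
    ccfg <- cpp_cfg(object$config, object$n_input)
    acc <- NULL
    for (p in object$fold_params) {
      pr <- pairnet_forward_cpp(p, ft$channels, ft$mask, ccfg)
      acc <- if (is.null(acc)) pr else acc + pr
    }
    pairing_prob_map(acc / length(object$fold_params))
  }
  if (inherits(newdata, "feature_tensor") ||
      (is.list(newdata) && (!is.null(newdata$features) ||
                            !is.null(newdata$map_a)))) {
    one(newdata)
  } else {
    lapply(newdata, one)
  }
}
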