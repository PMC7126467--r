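#' @export
print.pairnet <- function(x, ...) {
  cat("Beta-beta pairing network (ensemble of fold models)\n")
  cat(sprintf("  architecture: %d blocks, %d channels, %s, %d input channels\n",
              x$config$n_blocks, x$config$n_channels,
              if (x$config$use_rncn) "RN/CN + IN" else "IN only",
              x$n_input))
  cat(sprintf("  folds trained: %d of %d\n", length(x$fold_params),
              x$control$n_folds))
  cat(sprintf("  operating cutoff (pooled out-of-fold F1): %.4f\n",
              x$cutoff))
  invisible(x)
}

#' @export
summary.pairnet <- function(object, ...) {
  h <- object$history
  per_fold <- do.call(rbind, lapply(split(h, h$fold), function(hf) {
    best <- hf[which.max(hf$val_f1), ]
    data.frame(fold = best$fold, epochs_run = max(hf$epoch),
               best_epoch = best$epoch, best_val_f1 = best$val_f1,
               cutoff = best$cutoff)
  }))
  out <- list(config = object$config, control = object$control,
              cutoff = object$cutoff, per_fold = per_fold,
              n_params = length(object$fold_params[[1]]))
  class(out) <- "summary.pairnet"
  out
}

#' @export
print.summary.pairnet <- function(x, ...) {
  cat("Beta-beta pairing network\n")
  cat(sprintf("  %d blocks, %d channels, %s; %d parameters per fold model\n",
              x$config$n_blocks, x$config$n_channels,
              if (x$config$use_rncn) "RN/CN + IN" else "IN only",
              x$n_params))
  cat(sprintf("  ensemble cutoff: %.4f\n", x$cutoff))
  cat("  per-fold validation summary:\n")
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pairnet <- function(object, fold = NULL, ...) {
  if (is.null(fold)) object$fold_params
  else object$fold_params[[fold]]
}

#' Plot training history
#'
#' Training loss and validation F1 per epoch, one line per fold.
#'
#' @param x A fitted `"pairnet"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pairnet <- function(x, ...) {
  h <- x$history
  folds <- sort(unique(h$fold))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  loss_w <- do.call(cbind, lapply(folds, function(f) {
    v <- h$train_loss[h$fold == f]
    c(v, rep(NA, max(table(h$fold)) - length(v)))
  }))
  f1_w <- do.call(cbind, lapply(folds, function(f) {
    v <- h$val_f1[h$fold == f]
    c(v, rep(NA, max(table(h$fold)) - length(v)))
  }))
  graphics::matplot(loss_w, type = "l", lty = 1, xlab = "epoch",
                    ylab = "training loss", main = "loss", ...)
  graphics::matplot(f1_w, type = "l", lty = 1, xlab = "epoch",
                    ylab = "validation F1", main = "held-out F1", ...)
  invisible(x)
}

#' Save / load a fitted ensemble
#'
#' Writes a directory with a JSON manifest (architecture, training
#' settings, selected cutoff, channel registry) and one plain-text weight
#' file per fold model.
#'
#' @param object A fitted `"pairnet"`.
#' @param dir Checkpoint directory.
#' @return `save_pairnet` returns `dir` invisibly; `load_pairnet` returns
#'   the restored `"pairnet"` object.
#' @export
save_pairnet <- function(object, dir) {
  stopifnot(inherits(object, "pairnet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = unclass(object$config),
    control = unclass(object$control),
    n_input = object$n_input,
    cutoff = object$cutoff,
    fold_ids = object$fold_ids,
    registry = object$registry)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (k in seq_along(object$fold_params)) {
    writeLines(sprintf("%.17g", object$fold_params[[k]]),
               file.path(dir, sprintf("fold%d_weights.txt", k)))
  }
  if (!is.null(object$history)) {
    write.table(object$history, file.path(dir, "history.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname save_pairnet
#' @export
load_pairnet <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  config <- do.call(pairnet_config, manifest$config)
  control <- do.call(train_control, manifest$control)
  files <- sort(list.files(dir, pattern = "^fold[0-9]+_weights\\.txt$",
                           full.names = TRUE))
  if (!length(files)) stop("no fold weight files in ", dir)
  params <- lapply(files, function(f) as.numeric(readLines(f)))
  hist_path <- file.path(dir, "history.tsv")
  history <- if (file.exists(hist_path)) {
    read.table(hist_path, sep = "\t", header = TRUE)
  } else NULL
  structure(list(fold_params = params,
                 fold_ids = manifest$fold_ids,
                 config = config, control = control,
                 n_input = manifest$n_input, cutoff = manifest$cutoff,
                 fold_of = NULL, history = history,
                 registry = manifest$registry),
            class = "pairnet")
}
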