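#' Method variants
#'
#' The five evaluated methods differ only in architecture and loss weights:
#' \describe{
#'   \item{proposed}{CNN-LSTM-attention, full composite loss (error +
#'     patient-invariance - unlabeled-separation).}
#'   \item{baseline}{Plain LSTM + two dense layers, error term only.}
#'   \item{only-mae}{CNN-LSTM-attention, error term only.}
#'   \item{no-patient}{Proposed without the patient-invariance term.}
#'   \item{no-unlabeled}{Proposed without the unlabeled-separation term.}
#' }
#'
#' @param variant Variant name.
#' @return List with `arch` and the three loss-weight multipliers.
#' @export
wallnet_variant <- function(variant = c("proposed", "baseline", "only-mae",
                                        "no-patient", "no-unlabeled")) {
  variant <- match.arg(variant)
  switch(variant,
    "proposed" = list(arch = "cla", weight_error = 1, weight_patient = 1,
                      weight_unlabeled = 1),
    "baseline" = list(arch = "lstm", weight_error = 1, weight_patient = 0,
                      weight_unlabeled = 0),
    "only-mae" = list(arch = "cla", weight_error = 1, weight_patient = 0,
                      weight_unlabeled = 0),
    "no-patient" = list(arch = "cla", weight_error = 1, weight_patient = 0,
                        weight_unlabeled = 1),
    "no-unlabeled" = list(arch = "cla", weight_error = 1, weight_patient = 1,
                          weight_unlabeled = 0))
}

#' Fit the wall-motion point classifier
#'
#' Trains the CNN-LSTM-attention regression network (sigmoid output scored
#' against 0/1 labels) with the Adam optimizer on the composite loss; see
#' [loss_config()] for the loss and [wallnet_variant()] for the ablation
#' variants. Features are z-scored per channel using statistics of the
#' training data only; the statistics are stored with the model and applied
#' by `predict()`. Each minibatch contains labeled points from at least two
#' patients (when the data has them) and, when the unlabeled-separation term
#' is active, a configurable number of unlabeled points. An optional early
#' stop monitors the error term on a held-out fraction of the labeled
#' training points.
#'
#' @param x Feature array `n x 5 x L` of the labeled points (see
#'   [build_feature_batch()]), or a `wm_features` object (in which case `y`
#'   and `patient` default to its labels/patients and unlabeled rows are
#'   split off automatically).
#' @param y Binary labels (0 TW, 1 HR).
#' @param patient Patient id per labeled point.
#' @param x_unlabeled Optional feature array of unlabeled points.
#' @param variant Method variant; sets architecture and loss weights (the
#'   weights multiply those in `loss`).
#' @param config A [wallnet_config()].
#' @param loss A [loss_config()].
#' @param epochs Training epochs; `epochs = 0` returns the initialized
#'   model.
#' @param batch_size Labeled points per minibatch.
#' @param unlabeled_per_batch Unlabeled points per minibatch (default half
#'   the batch size; ignored when the unlabeled term is off).
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters.
#' @param validation_split Fraction of labeled points held out for early
#'   stopping (0 disables).
#' @param patience Early-stopping patience in epochs.
#' @param seed RNG seed: initialization, batch order and validation split
#'   are reproducible given the seed.
#' @param verbose Print per-epoch loss breakdown.
#' @return Object of class `wallnet`.
#' @export
wallnet <- function(x, y = NULL, patient = NULL, x_unlabeled = NULL,
                    variant = "proposed", config = wallnet_config(),
                    loss = loss_config(), epochs = 30L, batch_size = 32L,
                    unlabeled_per_batch = NULL, lr = 1e-3, beta1 = 0.9,
                    beta2 = 0.999, adam_eps = 1e-8, validation_split = 0.1,
                    patience = 10L, seed = 1L, verbose = FALSE) {
  if (inherits(x, "wm_features")) {
    lab <- !is.na(x$y)
    if (is.null(x_unlabeled) && any(!lab))
      x_unlabeled <- x$x[!lab, , , drop = FALSE]
    y <- y %||% x$y[lab]
    patient <- patient %||% x$patient[lab]
    x <- x$x[lab, , , drop = FALSE]
  }
  if (is.null(y) || is.null(patient))
    stop("y and patient are required")
  if (length(y) == 0) stop("empty labeled set")
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  v <- wallnet_variant(variant)
  if (config$arch != v$arch) {
    config$arch <- v$arch
  }
  loss$weight_patient <- loss$weight_patient * v$weight_patient
  loss$weight_unlabeled <- loss$weight_unlabeled * v$weight_unlabeled
  if (loss$weight_patient > 0 && length(unique(patient)) < 2)
    stop("the patient-invariance term needs points from >= 2 patients")
  if (is.null(x_unlabeled) || loss$weight_unlabeled == 0)
    x_unlabeled <- array(0, c(0, dim(x)[2], dim(x)[3]))
  n_unl <- dim(x_unlabeled)[1]
  if (is.null(unlabeled_per_batch))
    unlabeled_per_batch <- ceiling(batch_size / 2)
  config$channels <- dim(x)[2]
  check_batch_shape(config, x)

  norm <- channel_norm_stats(
    if (n_unl > 0) abind3(x, x_unlabeled) else x)
  xs <- normalize_features(x, norm)
  xu <- if (n_unl > 0) normalize_features(x_unlabeled, norm) else x_unlabeled

  params <- wallnet_init(config, seed = seed)
  model <- structure(list(params = params, config = config, norm = norm,
                          loss = loss, variant = variant, seed = seed,
                          history = NULL, fitted = NULL, y = y,
                          patient = patient),
                     class = "wallnet")
  if (epochs == 0) return(model)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(seed, 1e6))

  n <- length(y)
  idx_val <- integer(0)
  if (validation_split > 0 && n >= 20) {
    nv <- max(2L, floor(validation_split * n))
    idx_val <- sort(sample.int(n, nv))
  }
  idx_tr <- setdiff(seq_len(n), idx_val)

  # Unlabeled minibatch indices come from a dedicated RNG stream so that the
  # labeled batch sequence is identical across method variants (paired
  # ablation runs differ only through the loss terms, not through batch
  # composition).
  use_unl <- n_unl > 0 && loss$weight_unlabeled > 0
  unl_state <- NULL
  if (use_unl) {
    set.seed(derive_seed(seed, 2e6))
    unl_state <- get_rng_state()
    set.seed(derive_seed(seed, 1e6))
  }
  draw_unl <- function() {
    a <- get_rng_state()
    restore_rng_state(unl_state)
    ui <- sample.int(n_unl, min(unlabeled_per_batch, n_unl))
    unl_state <<- get_rng_state()
    restore_rng_state(a)
    ui
  }

  m_st <- lapply(params, function(p) numeric(length(p)))
  v_st <- lapply(params, function(p) numeric(length(p)))
  step <- 0
  best_val <- Inf; best_params <- params; wait <- 0
  hist <- list()

  for (ep in seq_len(epochs)) {
    ord <- sample(idx_tr)
    nb <- max(1L, floor(length(ord) / batch_size))
    terms <- matrix(0, nb, 4)
    for (b in seq_len(nb)) {
      bi <- ord[((b - 1) * batch_size + 1):min(b * batch_size, length(ord))]
      # guarantee a cross-patient pair when the invariance term is active
      if (loss$weight_patient > 0 && length(unique(patient[bi])) < 2) {
        other <- idx_tr[patient[idx_tr] != patient[bi[1]]]
        if (length(other) > 0) bi[length(bi)] <- other[sample.int(length(other), 1)]
      }
      ui <- if (use_unl) draw_unl() else integer(0)
      xb <- xs[bi, , , drop = FALSE]
      fl <- cpp_nn_forward_cache(params, config$arch, xb)
      fu <- NULL
      if (length(ui) > 0) {
        xub <- xu[ui, , , drop = FALSE]
        fu <- cpp_nn_forward_cache(params, config$arch, xub)
        eu <- fu$embed
      } else eu <- matrix(0, 0, config$embedding_dim)
      sc <- as.numeric(fl$score)
      lv <- composite_loss(sc, y[bi], patient[bi], fl$embed, eu, loss)
      g <- composite_loss_grad(sc, y[bi], patient[bi], fl$embed, eu, loss)
      gl <- cpp_nn_backward_cache(fl$cache, params, g$dscore, g$dlabeled)
      if (length(ui) > 0) {
        gu <- cpp_nn_backward_cache(fu$cache, params,
                                    rep(0, length(ui)), g$dunlabeled)
        for (nm in names(gl)) gl[[nm]] <- gl[[nm]] + gu[[nm]]
      }
      step <- step + 1
      for (nm in names(params)) {
        gvec <- as.numeric(gl[[nm]])
        m_st[[nm]] <- beta1 * m_st[[nm]] + (1 - beta1) * gvec
        v_st[[nm]] <- beta2 * v_st[[nm]] + (1 - beta2) * gvec^2
        mh <- m_st[[nm]] / (1 - beta1^step)
        vh <- v_st[[nm]] / (1 - beta2^step)
        params[[nm]][] <- as.numeric(params[[nm]]) -
          lr * mh / (sqrt(vh) + adam_eps)
      }
      terms[b, ] <- c(lv$total, lv$error, lv$patient, lv$unlabeled)
    }
    val_err <- NA_real_
    if (length(idx_val) > 0) {
      fv <- cpp_nn_forward(params, config$arch, xs[idx_val, , , drop = FALSE])
      val_err <- error_term(as.numeric(fv$score), y[idx_val],
                            loss$error_term)
      if (val_err < best_val - 1e-9) {
        best_val <- val_err; best_params <- params; wait <- 0
      } else wait <- wait + 1
    }
    hist[[ep]] <- c(epoch = ep, total = mean(terms[, 1]),
                    error = mean(terms[, 2]), patient = mean(terms[, 3]),
                    unlabeled = mean(terms[, 4]), val_error = val_err)
    if (verbose)
      message(sprintf(
        "epoch %3d  total %.4f  err %.4f  Lp %.4f  Lm %.4f  val %.4f",
        ep, mean(terms[, 1]), mean(terms[, 2]), mean(terms[, 3]),
        mean(terms[, 4]), val_err))
    if (length(idx_val) > 0 && wait >= patience) break
  }
  if (length(idx_val) > 0 && is.finite(best_val)) params <- best_params

  model$params <- params
  model$history <- as.data.frame(do.call(rbind, hist))
  ff <- cpp_nn_forward(params, config$arch, xs)
  model$fitted <- as.numeric(ff$score)
  model
}

abind3 <- function(a, b) {
  d <- dim(a); db <- dim(b)
  stopifnot(d[2] == db[2], d[3] == db[3])
  out <- array(0, c(d[1] + db[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  if (db[1] > 0) out[d[1] + seq_len(db[1]), , ] <- b
  out
}

#' @export
print.wallnet <- function(x, ...) {
  cat(sprintf("<wallnet: variant '%s', arch '%s', %d labeled points, %d patients>\n",
              x$variant, x$config$arch, length(x$y),
              length(unique(x$patient))))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, final error term %.4f\n",
                nrow(x$history), x$history$error[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.wallnet <- function(object, ...) {
  cat("Wall-motion point classifier (CNN-LSTM-attention regressor)\n")
  print(object)
  npar <- sum(vapply(object$params, length, integer(1)))
  cat(sprintf("  parameters: %d  embedding dim: %d\n", npar,
              object$config$embedding_dim))
  cat(sprintf("  loss: %s error, w = (%g, %g, %g), margin %g\n",
              object$loss$error_term, object$loss$weight_error,
              object$loss$weight_patient, object$loss$weight_unlabeled,
              object$loss$margin))
  if (!is.null(object$fitted)) {
    acc <- mean((object$fitted > 0.5) == (object$y == 1)) * 100
    cat(sprintf("  training accuracy at threshold 0.5: %.2f%%\n", acc))
  }
  invisible(object)
}

#' Predict from a fitted wallnet model
#'
#' @param object A [wallnet()] fit.
#' @param x Feature array `n x 5 x L` (raw scale; the stored normalization
#'   is applied) or a `wm_features` object.
#' @param type `"score"` (sigmoid output in \[0,1\]), `"label"` (thresholded
#'   at 0.5), `"embedding"` (dense_1 activations) or `"attention"` (average
#'   attention map).
#' @param ... Unused.
#' @return Vector or matrix according to `type`.
#' @export
predict.wallnet <- function(object, x, type = c("score", "label",
                                                "embedding", "attention"),
                            ...) {
  type <- match.arg(type)
  if (inherits(x, "wm_features")) x <- x$x
  if (type == "attention") return(attention_map(object, x))
  xs <- normalize_features(x, object$norm)
  out <- cpp_nn_forward(object$params, object$config$arch, xs)
  switch(type,
         score = as.numeric(out$score),
         label = predict_labels(as.numeric(out$score)),
         embedding = out$embed)
}

#' @export
coef.wallnet <- function(object, ...) object$params

#' @export
residuals.wallnet <- function(object, ...) {
  if (is.null(object$fitted)) stop("model has no fitted values")
  object$y - object$fitted
}

#' @export
plot.wallnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$total, h$error), type = "l", lty = 1,
                    col = c("black", "firebrick"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", c("total", "error term"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
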