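#' Network architecture configuration
#'
#' Describes the CNN-LSTM-attention regressor: two 1-D convolution blocks
#' (ReLU, stride 1, zero "same" padding), an LSTM returning its full hidden
#' sequence, additive (tanh-scored) temporal attention layers, a dense
#' embedding layer (`dense_1`, ReLU) and a sigmoid scalar output. One
#' attention layer pools each conv block's output and one pools the LSTM
#' sequence (three in total); their context vectors are concatenated and fed
#' to `dense_1`. The alternative `arch = "lstm"` is the ablation baseline: an
#' LSTM over the raw channels followed by two dense layers, with no
#' convolution and no attention.
#'
#' @param filters Number of filters in each convolution block.
#' @param kernel Odd kernel size of the 1-D convolutions.
#' @param lstm_units LSTM hidden-state width.
#' @param attention_dim Width of the additive attention scoring layer.
#' @param embedding_dim Width of the `dense_1` embedding layer on which the
#'   auxiliary loss terms operate.
#' @param channels Number of input feature channels (5 for the kinematic
#'   features: speed, acceleration, and the three planar angles).
#' @param arch `"cla"` (conv-LSTM-attention) or `"lstm"` (baseline).
#' @return An object of class `wallnet_config`.
#' @export
wallnet_config <- function(filters = 64L, kernel = 3L, lstm_units = 64L,
                           attention_dim = 32L, embedding_dim = 32L,
                           channels = 5L, arch = c("cla", "lstm")) {
  arch <- match.arg(arch)
  dims <- c(filters = filters, kernel = kernel, lstm_units = lstm_units,
            attention_dim = attention_dim, embedding_dim = embedding_dim,
            channels = channels)
  if (any(dims < 1) || any(dims != round(dims)))
    stop("all architecture dimensions must be positive integers")
  if (kernel %% 2 != 1) stop("kernel size must be odd (same padding)")
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 lstm_units = as.integer(lstm_units),
                 attention_dim = as.integer(attention_dim),
                 embedding_dim = as.integer(embedding_dim),
                 channels = as.integer(channels), arch = arch),
            class = "wallnet_config")
}

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

#' Initialize network parameters
#'
#' All weight matrices are drawn from the Glorot (Xavier) uniform
#' distribution, +/- sqrt(6 / (fan_in + fan_out)); all biases start at zero.
#' Deterministic given `seed`.
#'
#' @param config A [wallnet_config()].
#' @param seed Integer RNG seed.
#' @return Named list of parameter arrays.
#' @export
wallnet_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "wallnet_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  C <- config$channels; F <- config$filters; k <- config$kernel
  H <- config$lstm_units; A <- config$attention_dim; E <- config$embedding_dim
  att_params <- function(D) {
    list(W = matrix(glorot_uniform(D, A, D * A), D, A),
         b = numeric(A),
         v = glorot_uniform(A, 1, A))
  }
  if (config$arch == "cla") {
    p <- list(
      conv1_W = array(glorot_uniform(C * k, F * k, C * F * k), c(C, F, k)),
      conv1_b = numeric(F),
      conv2_W = array(glorot_uniform(F * k, F * k, F * F * k), c(F, F, k)),
      conv2_b = numeric(F))
    a1 <- att_params(F); a2 <- att_params(F)
    p$att1_W <- a1$W; p$att1_b <- a1$b; p$att1_v <- a1$v
    p$att2_W <- a2$W; p$att2_b <- a2$b; p$att2_v <- a2$v
    p$lstm_Wx <- matrix(glorot_uniform(F, 4 * H, F * 4 * H), F, 4 * H)
    p$lstm_Wh <- matrix(glorot_uniform(H, 4 * H, H * 4 * H), H, 4 * H)
    p$lstm_b <- numeric(4 * H)
    a3 <- att_params(H)
    p$att3_W <- a3$W; p$att3_b <- a3$b; p$att3_v <- a3$v
    din <- 2 * F + H
    p$d1_W <- matrix(glorot_uniform(din, E, din * E), din, E)
    p$d1_b <- numeric(E)
    p$out_W <- matrix(glorot_uniform(E, 1, E), E, 1)
    p$out_b <- 0
  } else {
    p <- list(
      lstm_Wx = matrix(glorot_uniform(C, 4 * H, C * 4 * H), C, 4 * H),
      lstm_Wh = matrix(glorot_uniform(H, 4 * H, H * 4 * H), H, 4 * H),
      lstm_b = numeric(4 * H),
      d1_W = matrix(glorot_uniform(H, E, H * E), H, E),
      d1_b = numeric(E),
      out_W = matrix(glorot_uniform(E, 1, E), E, 1),
      out_b = 0)
  }
  p
}

#' Forward pass of the network
#'
#' Pure function: no state is mutated and repeated calls agree bitwise.
#'
#' @param params Parameter list from [wallnet_init()] (or a trained model's
#'   `$params`).
#' @param config The matching [wallnet_config()].
#' @param x Numeric array `n x channels x L` of (already normalized) feature
#'   series.
#' @return List with `score` (length-n vector in \[0,1\]), `embed`
#'   (`n x embedding_dim` matrix of dense_1 activations) and `att`
#'   (`n x L x n_att` array of per-layer attention weights; zero layers for
#'   the baseline architecture).
#' @export
wallnet_forward <- function(params, config, x) {
  stopifnot(inherits(config, "wallnet_config"))
  check_batch_shape(config, x)
  out <- cpp_nn_forward(params, config$arch, x)
  out$score <- as.numeric(out$score)
  out
}

check_batch_shape <- function(config, x) {
  d <- dim(x)
  if (length(d) != 3)
    stop("feature batch must be a 3-d array (samples x channels x time)")
  if (d[2] != config$channels)
    stop(sprintf("batch has %d channels but the model expects %d",
                 d[2], config$channels))
  invisible(TRUE)
}

#' Average attention map
#'
#' Averages the per-layer temporal attention weights of the network for each
#' sample, giving one non-negative weight per time step that sums to one.
#' These maps can be used to color trajectories by the time segments the
#' model attends to. The baseline architecture has no attention layers and
#' returns a uniform map.
#'
#' @param model A fitted [wallnet()] model (or a list with `params`, `config`
#'   and `norm` entries).
#' @param x Feature array `n x channels x L` on the *raw* (unnormalized)
#'   scale if `model$norm` is present, otherwise already normalized.
#' @return `n x L` matrix; each row sums to 1.
#' @export
attention_map <- function(model, x) {
  x <- normalize_features(x, model$norm)
  out <- cpp_nn_forward(model$params, model$config$arch, x)
  att <- out$att
  L <- dim(x)[3]
  if (length(att) == 0 || dim(att)[3] == 0)
    return(matrix(1 / L, nrow = dim(x)[1], ncol = L))
  apply(att, c(1, 2), mean)
}

# Per-channel z-score statistics, computed from training data only.
channel_norm_stats <- function(x) {
  m <- apply(x, 2, mean)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = m, sd = s)
}

normalize_features <- function(x, norm) {
  if (is.null(norm)) return(x)
  for (ch in seq_len(dim(x)[2]))
    x[, ch, ] <- (x[, ch, ] - norm$mean[ch]) / norm$sd[ch]
  x
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a child seed from a master seed and an index; stays below 2^31.
derive_seed <- function(master, index) {
  m <- as.numeric(master) %% 2147483563
  as.integer((m * 48271 + as.numeric(index) * 30269 + 17) %% 2147483563) + 1L
}
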