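# Independent brute-force oracles and small fixture builders shared across
# the test files. Each oracle deliberately uses a different algorithm (and
# code path) than the implementation it checks.

# Exhaustive-recursion DTW: minimum over all monotone warping paths, no
# dynamic-programming table. Only feasible for short series.
dtw_enum_oracle <- function(a, b) {
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == length(a) && j == length(b)) return(cost)
    best <- Inf
    if (i < length(a)) best <- min(best, rec(i + 1, j))
    if (j < length(b)) best <- min(best, rec(i, j + 1))
    if (i < length(a) && j < length(b)) best <- min(best, rec(i + 1, j + 1))
    cost + best
  }
  rec(1, 1)
}

# Sup of |ECDF_a - ECDF_b| over the pooled sample grid.
ks_stat_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(t) mean(a <= t), numeric(1))
  fb <- vapply(grid, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

# Exact integral of |ECDF_a - ECDF_b| over the value axis (piecewise
# constant between pooled sorted values).
wasserstein_ecdf_oracle <- function(a, b) {
  x <- sort(unique(c(a, b)))
  if (length(x) == 1) return(0)
  fa <- vapply(x, function(t) mean(a <= t), numeric(1))
  fb <- vapply(x, function(t) mean(b <= t), numeric(1))
  k <- length(x)
  sum(abs(fa[-k] - fb[-k]) * diff(x))
}

# Per-query O(n) scan nearest neighbour with first-index tie break.
nearest_oracle <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- colSums((t(ref) - query[i, ])^2)
    which(d2 == min(d2))[1]
  }, integer(1))
}

# Signed atan2 planar angle folded to [0, pi].
angle_atan2_oracle <- function(a, b, c) {
  u <- a - b; v <- c - b
  abs(atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2]))
}

# Hand confusion-matrix metrics (support-weighted, percent scale).
metrics_oracle <- function(y_true, y_pred) {
  tab <- matrix(0, 2, 2)
  for (i in seq_along(y_true))
    tab[y_true[i] + 1, y_pred[i] + 1] <- tab[y_true[i] + 1, y_pred[i] + 1] + 1
  acc <- sum(diag(tab)) / sum(tab)
  out <- c(0, 0, 0)
  for (cls in 1:2) {
    sup <- sum(tab[cls, ])
    if (sup == 0) next
    p <- if (sum(tab[, cls]) > 0) tab[cls, cls] / sum(tab[, cls]) else 0
    r <- tab[cls, cls] / sup
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out <- out + sup / sum(tab) * c(p, r, f)
  }
  c(accuracy = acc, precision = out[1], recall = out[2], f1 = out[3]) * 100
}

# Pair-loop oracles for the auxiliary loss terms.
lp_oracle <- function(emb, labels, patients) {
  n <- nrow(emb); s <- 0; k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j] && patients[i] != patients[j]) {
      s <- s + sqrt(sum((emb[i, ] - emb[j, ])^2)); k <- k + 1
    }
  }
  if (k == 0) 0 else s / k
}

lm_oracle <- function(el, eu, m) {
  if (nrow(el) == 0 || nrow(eu) == 0) return(0)
  s <- 0
  for (i in seq_len(nrow(el))) for (j in seq_len(nrow(eu)))
    s <- s + min(sqrt(sum((el[i, ] - eu[j, ])^2)), m)
  s / (nrow(el) * nrow(eu))
}

# Small network configuration used throughout the tests; keeps runtimes low
# while exercising every layer type.
small_config <- function(arch = "cla") {
  wallnet_config(filters = 8, lstm_units = 8, attention_dim = 8,
                 embedding_dim = 8, arch = arch)
}

tiny_config <- function(arch = "cla", channels = 3) {
  wallnet_config(filters = 4, kernel = 3, lstm_units = 4, attention_dim = 3,
                 embedding_dim = 4, channels = channels, arch = arch)
}

# Small synthetic cohort; defaults keep training tests fast.
small_cohort <- function(n_patients = 4, tw = 40, hr = 40, unlabeled = 20,
                         separability = 2, patient_scale_sd = 0.3,
                         hard_fraction = 0, seed = 11) {
  params <- wall_motion_params(separability = separability,
                               patient_scale_sd = patient_scale_sd)
  simulate_cohort(n_patients,
                  c(tw = tw, hr = hr, unlabeled = unlabeled),
                  params = params, hard_fraction = hard_fraction,
                  seed = seed)
}

helix_trajectory <- function(rate = 100, duration = 1) {
  tt <- seq(0, duration, by = 1 / rate)
  wm_trajectory(cbind(cos(2 * pi * tt), sin(2 * pi * tt), tt), rate = rate)
}

rigid_rotation <- function() {
  # a generic rotation (no axis-aligned symmetry)
  ax <- c(1, 2, 3) / sqrt(14); th <- 0.7
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
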