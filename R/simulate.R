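#' Synthetic pulsatile wall-motion parameters
#'
#' Describes the generative model of the synthetic cohort: each wall point
#' oscillates about an anchor along a random direction as a sum of cardiac
#' harmonics, with isotropic Gaussian jitter on top. Thin-walled (TW) points
#' move with larger amplitude; hyperplastic-remodeling (HR) points have their
#' jitter suppressed (smoother motion). The separability parameter `delta`
#' scales the TW-vs-HR parameter gap: `delta = 0` makes the two generating
#' distributions identical, larger values pull them apart in speed,
#' acceleration and angle variability simultaneously. Per-patient log-normal
#' multipliers on amplitude and frequency emulate patient heterogeneity.
#'
#' Defaults: a 1 Hz fundamental (cardiac rate) sampled at 100 Hz for 1 s,
#' 0.2 mm base amplitude with three 1/h-decaying harmonics, 0.02 mm jitter,
#' and anchor points in a 10 mm cube. Units are mm and seconds throughout.
#'
#' @param fundamental_freq Cardiac fundamental frequency (Hz).
#' @param n_harmonics Number of harmonics.
#' @param base_amplitude Displacement amplitude of the fundamental (mm).
#' @param tw_amplitude_gain Amplitude multiplier of TW relative to HR
#'   (>= 1).
#' @param hr_smoothness_gain Factor by which HR jitter is suppressed (>= 1).
#' @param jitter_sd Isotropic jitter standard deviation (mm).
#' @param separability Non-negative `delta` scaling the class gap.
#' @param patient_scale_sd Log-sd of the per-patient *amplitude* multiplier.
#' @param patient_freq_sd Log-sd of the per-patient *frequency* (heart-rate)
#'   multiplier. Cardiac rate varies considerably between patients while
#'   wall-motion amplitude varies more modestly, so the two latent factors
#'   get separate spreads; frequency heterogeneity also leaves an invariant
#'   feature combination intact (speed^2 / acceleration cancels the rate),
#'   which is what patient-invariant feature learning can exploit.
#' @param duration Trajectory duration (s).
#' @param rate Sampling rate (Hz); `rate * duration` must be an integer.
#' @return Object of class `wm_params`.
#' @export
wall_motion_params <- function(fundamental_freq = 1, n_harmonics = 3L,
                               base_amplitude = 0.2, tw_amplitude_gain = 2,
                               hr_smoothness_gain = 2, jitter_sd = 0.02,
                               separability = 1, patient_scale_sd = 0.15,
                               patient_freq_sd = 0.25,
                               duration = 1, rate = 100) {
  if (rate <= 0 || duration <= 0) stop("rate and duration must be positive")
  nt <- rate * duration
  if (abs(nt - round(nt)) > 1e-9)
    stop("rate * duration must be an integer sample count")
  if (base_amplitude < 0 || jitter_sd < 0 || separability < 0 ||
      patient_scale_sd < 0 || patient_freq_sd < 0)
    stop("amplitudes, variances and separability must be >= 0")
  if (tw_amplitude_gain < 1 || hr_smoothness_gain < 1)
    stop("class gains must be >= 1")
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  structure(list(fundamental_freq = fundamental_freq,
                 n_harmonics = as.integer(n_harmonics),
                 base_amplitude = base_amplitude,
                 tw_amplitude_gain = tw_amplitude_gain,
                 hr_smoothness_gain = hr_smoothness_gain,
                 jitter_sd = jitter_sd, separability = separability,
                 patient_scale_sd = patient_scale_sd,
                 patient_freq_sd = patient_freq_sd, duration = duration,
                 rate = rate),
            class = "wm_params")
}

# Class coordinate u: 1 = TW extreme, 0 = HR extreme. Unlabeled points draw
# u uniformly, i.e. an interpolation between the two parameter sets.
class_generating_pars <- function(params, u) {
  d <- params$separability
  list(amp_gain = 1 + u * d * (params$tw_amplitude_gain - 1),
       jitter = params$jitter_sd /
         (1 + (1 - u) * d * (params$hr_smoothness_gain - 1)))
}

#' Simulate one wall-point trajectory
#'
#' @param params A [wall_motion_params()].
#' @param cls `"TW"`, `"HR"` or `"unlabeled"`.
#' @param patient_factors List with `amp` and `freq` multipliers (and
#'   optionally `id`), as produced per patient by [simulate_cohort()].
#' @param seed Integer seed; the trajectory is deterministic given
#'   `(params, cls, patient_factors, seed)`.
#' @param point_id Identifier for the generated point.
#' @return A [wm_trajectory()].
#' @export
simulate_trajectory <- function(params, cls = c("TW", "HR", "unlabeled"),
                                patient_factors = list(amp = 1, freq = 1,
                                                       id = "pat1"),
                                seed = 1L, point_id = "p1") {
  stopifnot(inherits(params, "wm_params"))
  cls <- match.arg(cls)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  u <- switch(cls, TW = 1, HR = 0, unlabeled = stats::runif(1))
  gp <- class_generating_pars(params, u)
  TT <- round(params$rate * params$duration)
  tt <- (seq_len(TT) - 1) / params$rate
  anchor <- stats::runif(3, 0, 10)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  disp <- numeric(TT)
  f0 <- params$fundamental_freq * patient_factors$freq
  for (h in seq_len(params$n_harmonics)) {
    ph <- stats::runif(1, 0, 2 * pi)
    ah <- params$base_amplitude * gp$amp_gain * patient_factors$amp / h
    disp <- disp + ah * sin(2 * pi * h * f0 * tt + ph)
  }
  jit <- matrix(stats::rnorm(TT * 3, 0, gp$jitter), TT, 3)
  coords <- matrix(anchor, TT, 3, byrow = TRUE) + outer(disp, dir) + jit
  lab <- switch(cls, TW = 0L, HR = 1L, unlabeled = NA_integer_)
  wm_trajectory(coords, rate = params$rate, point_id = point_id,
                patient_id = patient_factors$id %||% "pat1", label = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a multi-patient cohort
#'
#' Patient latent factors (log-normal amplitude and frequency multipliers)
#' are drawn once per patient from a per-patient seed derived from the
#' master seed, so cohorts are stable under patient-count changes and
#' byte-identical across calls with the same master seed. A fraction of
#' "hard" patients is generated with the separability `delta` shrunk by
#' `hard_factor` (default 0.1), emulating patients whose TW and HR motion
#' distributions nearly coincide. Hard status is assigned to the first
#' `round(hard_fraction * n_patients)` patients.
#'
#' @param n_patients Number of patients (>= 1).
#' @param per_patient_counts Named vector `c(tw=, hr=, unlabeled=)` of
#'   trajectories per patient. Defaults mirror a cohort with 2,000 labeled
#'   trajectories per patient and a 3:2 unlabeled:labeled ratio.
#' @param params A [wall_motion_params()].
#' @param hard_fraction Fraction of hard patients in `[0, 1]`.
#' @param hard_factor Multiplier applied to `delta` for hard patients.
#' @param seed Master seed.
#' @param dir Optional output directory: per-patient trajectory CSVs plus a
#'   YAML manifest are written there.
#' @return Object of class `wm_cohort`: list with `trajectories` (list of
#'   [wm_trajectory()]) and `manifest` (patients, counts, latent factors,
#'   seeds, file paths).
#' @export
simulate_cohort <- function(n_patients, per_patient_counts = c(tw = 1000,
                            hr = 1000, unlabeled = 3000),
                            params = wall_motion_params(), hard_fraction = 0,
                            hard_factor = 0.1, seed = 1L, dir = NULL) {
  stopifnot(inherits(params, "wm_params"))
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (hard_fraction < 0 || hard_fraction > 1)
    stop("hard_fraction must be in [0, 1]")
  cts <- per_patient_counts
  for (nm in c("tw", "hr", "unlabeled")) if (is.na(cts[nm])) cts[nm] <- 0
  cts <- cts[c("tw", "hr", "unlabeled")]
  if (any(cts < 0)) stop("counts must be >= 0")
  if (any(cts[c("tw", "hr")] == 0))
    warning("a labeled class has zero count in every patient")
  n_hard <- round(hard_fraction * n_patients)

  trajectories <- list()
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pid <- sprintf("pat%02d", i)
    pseed <- derive_seed(seed, i)
    old <- get_rng_state()
    set.seed(pseed)
    factors <- list(amp = stats::rlnorm(1, 0, params$patient_scale_sd),
                    freq = stats::rlnorm(1, 0, params$patient_freq_sd),
                    id = pid)
    restore_rng_state(old)
    hard <- i <= n_hard
    pp <- params
    if (hard) pp$separability <- params$separability * hard_factor
    k <- 0
    ptr <- list()
    for (cls in c("TW", "HR", "unlabeled")) {
      nc <- cts[c(TW = "tw", HR = "hr", unlabeled = "unlabeled")[cls]]
      for (j in seq_len(nc)) {
        k <- k + 1
        ptr[[k]] <- simulate_trajectory(
          pp, cls, factors, seed = derive_seed(pseed, k),
          point_id = sprintf("%s_%04d", pid, k))
      }
    }
    trajectories <- c(trajectories, ptr)
    patients[[i]] <- list(id = pid, hard = hard, seed = pseed,
                          amp = factors$amp, freq = factors$freq,
                          counts = as.list(cts))
  }
  manifest <- list(master_seed = as.integer(seed),
                   n_patients = as.integer(n_patients),
                   hard_fraction = hard_fraction, hard_factor = hard_factor,
                   params = unclass(params), patients = patients)
  cohort <- structure(list(trajectories = trajectories, manifest = manifest),
                      class = "wm_cohort")
  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  cohort
}

#' @export
print.wm_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<wm_cohort: %d patients, %d trajectories (%d hard patients)>\n",
              m$n_patients, length(x$trajectories),
              sum(vapply(m$patients, function(p) p$hard, logical(1)))))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One trajectory CSV per patient plus `manifest.yaml`.
#'
#' @param cohort A `wm_cohort`.
#' @param dir Output directory (created if needed).
#' @return The cohort with file paths recorded in the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pats <- vapply(cohort$manifest$patients, function(p) p$id, character(1))
  by_pat <- split(cohort$trajectories,
                  vapply(cohort$trajectories, function(tr) tr$patient_id,
                         character(1)))
  for (i in seq_along(pats)) {
    f <- file.path(dir, paste0(pats[i], ".csv"))
    write_trajectories(by_pat[[pats[i]]], f)
    cohort$manifest$patients[[i]]$file <- basename(f)
  }
  yaml::write_yaml(cohort$manifest, file.path(dir, "manifest.yaml"))
  invisible(cohort)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.yaml`.
#' @return A `wm_cohort`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", dir)
  manifest <- yaml::read_yaml(mf)
  trajectories <- list()
  for (p in manifest$patients) {
    f <- file.path(dir, p$file)
    if (!file.exists(f)) stop("manifest references missing file: ", p$file)
    trajectories <- c(trajectories, read_trajectories(f))
  }
  structure(list(trajectories = trajectories, manifest = manifest),
            class = "wm_cohort")
}

#' Labels of a cohort's trajectories
#' @param cohort A `wm_cohort`.
#' @return Integer vector (0 TW, 1 HR, NA unlabeled).
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$trajectories, function(tr) tr$label, integer(1))
}

#' Patient ids of a cohort's trajectories
#' @param cohort A `wm_cohort`.
#' @return Character vector.
#' @export
cohort_patients <- function(cohort) {
  vapply(cohort$trajectories, function(tr) tr$patient_id, character(1))
}
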