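# Seeded generator of labeled walking recordings. Stands in for insole +
# IMU hardware: emits per-sample ground-truth phases, 3-channel FSR analog
# traces per foot, and a panel of feature channels whose conditional means
# differ by phase, so the downstream classifier has signal to find.

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# default fraction of one gait cycle spent in each sub-phase; toe off
# occupies 1.6% of a cycle, the other stance fractions follow standard
# gait proportions (swing ~40% of the cycle)
default_phase_fractions <- function() {
  c(SW = 0.40, HS = 0.10, FC = 0.35, HO = 0.134, TO = 0.016)
}

#' Create a synthetic gait profile
#'
#' A `gait_profile` bundles every parameter of the synthetic walking
#' generator: walking speed, cadence, per-phase cycle fractions, the number of
#' feature channels, noise scales, and the seeded per-subject quantities
#' (constant channel offsets, per-phase channel means, sinusoid phases).
#' Identical `seed` and parameters give bit-identical profiles and, through
#' [simulate_walk()], bit-identical recordings.
#'
#' @param seed integer seed; drives all subject-specific randomness.
#' @param speed_mps walking speed in m/s; must lie within `speed_band`.
#' @param overrides named list overriding any of: `cadence_hz` (steps per
#'   second; default scales with speed), `phase_fractions` (named vector over
#'   SW/HS/FC/HO/TO, must sum to 1), `n_feature_channels` (default 22),
#'   `noise_sigma` (additive Gaussian noise scale per channel, default 0.05 of
#'   the unit channel amplitude), `fsr_noise_sigma` (FSR analog noise, default
#'   0.03), `speed_band` (default `c(0.2, 1.5)` m/s).
#' @return object of class `gait_profile`.
#' @export
#' @examples
#' p <- make_gait_profile(seed = 1, speed_mps = 1.0)
#' p$phase_fractions[["TO"]]  # 0.016, i.e. ~1.6% of one cycle
make_gait_profile <- function(seed, speed_mps = 1.0, overrides = list()) {
  known <- c("cadence_hz", "phase_fractions", "n_feature_channels",
             "noise_sigma", "fsr_noise_sigma", "speed_band")
  bad <- setdiff(names(overrides), known)
  check_that(length(bad) == 0L,
             "unknown profile override(s): ", paste(bad, collapse = ", "))
  speed_band <- overrides$speed_band %||% c(0.2, 1.5)
  check_that(speed_mps >= speed_band[1L] && speed_mps <= speed_band[2L],
             "speed_mps = ", speed_mps, " outside the configured band [",
             speed_band[1L], ", ", speed_band[2L], "] m/s")
  fractions <- overrides$phase_fractions %||% default_phase_fractions()
  check_that(length(fractions) == 5L &&
               setequal(names(fractions), names(PHASES)),
             "phase_fractions must be named over SW, HS, FC, HO, TO")
  fractions <- fractions[names(PHASES)]
  check_that(all(fractions > 0), "phase fractions must be positive")
  check_that(abs(sum(fractions) - 1) <= 1e-9,
             "phase fractions must sum to 1 (got ", sum(fractions), ")")
  n_chan <- as.integer(overrides$n_feature_channels %||% 22L)
  check_that(n_chan >= 1L, "need at least one feature channel")
  # cadence rises with speed; ~2 steps/s at 1 m/s is a normal walking pace
  cadence <- overrides$cadence_hz %||% (1.2 + 0.8 * speed_mps)
  check_that(cadence > 0, "cadence_hz must be positive")
  noise_sigma <- overrides$noise_sigma %||% 0.05
  check_that(noise_sigma >= 0, "noise_sigma must be non-negative")

  subj <- with_seed(as.integer(seed), list(
    subject_offset = stats::rnorm(n_chan, 0, 0.2),
    # per-phase, per-channel mean levels on a unit amplitude scale
    phase_means = matrix(stats::runif(5L * n_chan, -1, 1), nrow = 5L,
                         dimnames = list(names(PHASES), NULL)),
    channel_phase = stats::runif(n_chan, 0, 2 * pi)
  ))

  structure(list(
    seed = as.integer(seed),
    speed_mps = speed_mps,
    speed_band = speed_band,
    cadence_hz = cadence,
    phase_fractions = fractions,
    n_feature_channels = n_chan,
    noise_sigma = noise_sigma,
    fsr_noise_sigma = overrides$fsr_noise_sigma %||% 0.03,
    subject_offset = subj$subject_offset,
    phase_means = subj$phase_means,
    channel_phase = subj$channel_phase
  ), class = "gait_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_profile <- function(x, ...) {
  cat("<gait_profile>\n")
  cat(sprintf("  seed %d, speed %.2f m/s, cadence %.2f steps/s, %d channels\n",
              x$seed, x$speed_mps, x$cadence_hz, x$n_feature_channels))
  cat("  phase fractions:",
      paste(sprintf("%s=%.3f", names(x$phase_fractions), x$phase_fractions),
            collapse = " "), "\n")
  invisible(x)
}

# samples in one full gait cycle (two steps) at the given sampling rate
cycle_samples_of <- function(profile, fs_hz) {
  max(5L, as.integer(round(fs_hz * 2 / profile$cadence_hz)))
}

#' Per-cycle phase schedule
#'
#' Allocates the samples of each gait cycle to the five sub-phases in the
#' fixed within-cycle order HS, FC, HO, TO, SW. Counts follow the profile's
#' phase fractions under largest-remainder rounding, and every phase is
#' guaranteed at least one sample per cycle (toe off is so short that plain
#' rounding could otherwise eliminate it).
#'
#' @param profile a [make_gait_profile()] object.
#' @param n_cycles number of cycles (>= 1).
#' @param fs_hz sampling rate in Hz (default 100).
#' @param cycle_samples optional explicit cycle length in samples; defaults to
#'   `round(fs_hz * 2 / cadence_hz)`.
#' @return data.frame with columns `cycle`, `phase` (code), `name`,
#'   `n_samples`; `sum(n_samples) == n_cycles * cycle_samples`.
#' @export
#' @examples
#' p <- make_gait_profile(1)
#' sched <- phase_schedule(p, 1, cycle_samples = 126)
#' sched$n_samples[sched$name == "TO"]  # 2 samples of toe off
phase_schedule <- function(profile, n_cycles, fs_hz = 100,
                           cycle_samples = NULL) {
  check_that(inherits(profile, "gait_profile"), "profile must be a gait_profile")
  check_that(n_cycles >= 1, "n_cycles must be >= 1")
  L <- as.integer(cycle_samples %||% cycle_samples_of(profile, fs_hz))
  check_that(L >= 5L, "cycle must hold at least one sample per phase")
  order_names <- c("HS", "FC", "HO", "TO", "SW")
  frac <- profile$phase_fractions[order_names]
  ideal <- frac * L
  alloc <- floor(ideal)
  deficit <- L - sum(alloc)
  if (deficit > 0) {
    take <- order(ideal - alloc, decreasing = TRUE)[seq_len(deficit)]
    alloc[take] <- alloc[take] + 1
  }
  while (any(alloc == 0)) {            # every phase gets >= 1 sample
    alloc[which(alloc == 0)[1L]] <- 1
    alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1
  }
  data.frame(
    cycle = rep(seq_len(n_cycles), each = 5L),
    phase = rep(unname(phase_code(order_names)), n_cycles),
    name = rep(order_names, n_cycles),
    n_samples = rep(as.integer(alloc), n_cycles)
  )
}

# analog FSR levels (heel, meta, toe) per phase; stance rolls over
# heel -> heel+meta -> meta+toe -> toe -> none
fsr_levels <- function() {
  rbind(SW = c(0.05, 0.05, 0.05),
        HS = c(0.90, 0.05, 0.05),
        FC = c(0.90, 0.90, 0.05),
        HO = c(0.05, 0.90, 0.90),
        TO = c(0.05, 0.05, 0.90))
}

#' Simulate a labeled walking recording
#'
#' Generates a `motion_recording`: per-sample timestamps at `fs_hz`,
#' ground-truth phases for both feet (the left foot lags the right by half a
#' cycle), 3-channel analog FSR traces per foot following the stance rollover,
#' and a feature panel in which each channel carries a phase-dependent mean
#' level (smoothed across phase transitions), a cycle-periodic sinusoid, a
#' constant subject offset, and additive Gaussian noise. The feature panel
#' emulates sagittal-plane foot/shank motion channels of the right leg, so
#' features co-vary with the right-foot phase.
#'
#' @param profile a [make_gait_profile()] object.
#' @param duration_s positive duration in seconds.
#' @param fs_hz sampling rate in Hz (default 100).
#' @return object of class `motion_recording`: list with `fs_hz`, `time_ms`
#'   (integer milliseconds, strictly increasing with constant step),
#'   `features` (n x channels matrix), `fsr_left`/`fsr_right` (n x 3 analog),
#'   `truth_left`/`truth_right` (ground-truth phase codes), and the `profile`.
#' @export
#' @examples
#' rec <- simulate_walk(make_gait_profile(1), duration_s = 5)
#' nrow(rec$features)  # 500 frames at 100 Hz
simulate_walk <- function(profile, duration_s, fs_hz = 100) {
  check_that(inherits(profile, "gait_profile"), "profile must be a gait_profile")
  check_that(is.numeric(duration_s) && duration_s > 0,
             "duration_s must be positive")
  n <- as.integer(round(duration_s * fs_hz))
  check_that(n >= 1L, "duration too short for one sample at ", fs_hz, " Hz")
  L <- cycle_samples_of(profile, fs_hz)
  n_cycles <- ceiling((n + L) / L) + 1L
  sched <- phase_schedule(profile, n_cycles, fs_hz = fs_hz)
  full <- rep.int(sched$phase, sched$n_samples)
  right <- full[seq_len(n)]
  left <- full[seq_len(n) + L %/% 2L]   # anti-phase: half a cycle later

  nc <- profile$n_feature_channels
  with_seed(profile$seed + 1L, {
    # phase-conditional mean track, smoothed so transitions are not steps
    mu <- profile$phase_means[right, , drop = FALSE]
    kern <- stats::dnorm(-3:3, sd = 1.2)
    kern <- kern / sum(kern)
    mu <- apply(mu, 2L, function(col)
      as.numeric(stats::filter(col, kern, sides = 2L, circular = TRUE)))
    t_cyc <- (seq_len(n) - 1L) / L
    periodic <- 0.3 * sin(outer(2 * pi * t_cyc, rep(1, nc)) +
                            matrix(profile$channel_phase, n, nc, byrow = TRUE))
    noise <- matrix(stats::rnorm(n * nc, 0, profile$noise_sigma), n, nc)
    features <- mu + periodic +
      matrix(profile$subject_offset, n, nc, byrow = TRUE) + noise
    colnames(features) <- sprintf("f%02d", seq_len(nc))

    lev <- fsr_levels()
    fsr_one <- function(phase_seq) {
      a <- lev[phase_seq, , drop = FALSE]
      a <- a + matrix(stats::rnorm(n * 3L, 0, profile$fsr_noise_sigma), n, 3L)
      pmin(pmax(a, 0), 1)
    }
    fsr_right <- fsr_one(right)
    fsr_left <- fsr_one(left)
  })
  colnames(fsr_right) <- colnames(fsr_left) <- c("heel", "meta", "toe")

  structure(list(
    fs_hz = fs_hz,
    time_ms = as.integer(round((seq_len(n) - 1L) * 1000 / fs_hz)),
    features = features,
    fsr_left = fsr_left,
    fsr_right = fsr_right,
    truth_left = unname(left),
    truth_right = unname(right),
    profile = profile
  ), class = "motion_recording")
}

#' @export
print.motion_recording <- function(x, ...) {
  n <- nrow(x$features)
  cat(sprintf("<motion_recording> %d frames @ %g Hz (%.1f s), %d channels\n",
              n, x$fs_hz, n / x$fs_hz, ncol(x$features)))
  tab <- table(factor(phase_name(x$truth_right), levels = names(PHASES)))
  cat("  right-foot phase counts:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
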