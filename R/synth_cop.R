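# Synthetic postural-sway generator.
#
# Emulates a six-subject, three-level stabilometric dataset so the whole
# classification pipeline can be exercised reproducibly.  Each channel is a
# discretized Ornstein-Uhlenbeck (OU) process -- the simplest mean-reverting
# stochastic process with COP-like dynamics -- plus a slow sinusoidal drift.
# Better balance control is modeled as lower noise intensity, so the
# per-level sigmas are strictly ordered sigma_H < sigma_M < sigma_N.

#' Parameters of the synthetic sway simulator
#'
#' @param preset `"easy"` (widely separated per-level sigmas, default) or
#'   `"hard"` (strongly overlapping sigmas); individual arguments override
#'   the preset.
#' @param theta Mean-reversion rate (1/s).
#' @param sigma Named noise intensities `c(H = , M = , N = )` in
#'   units/sqrt(s); must be strictly increasing H < M < N.
#' @param drift_amp Amplitude of the additive low-frequency drift (units).
#' @param drift_freq Drift frequency (Hz).
#' @param subject_jitter Multiplicative per-subject spread on sigma
#'   (fraction; subject `i` of a level gets `sigma * (1 + jitter * u)` with
#'   a fixed seeded draw `u` in `[-1, 1]`).
#' @param fs Sampling rate (Hz).
#' @param duration Recording length (s); the default supplies any standard
#'   task (1200 + 600 windows across 3 subjects at stride 100) with the
#'   leakage gap.
#' @param seed Integer seed; every subject derives its own stream from it.
#' @return An object of class `sway_params`.
#' @export
sway_params <- function(preset = c("easy", "hard"), theta = 1.0,
                        sigma = NULL, drift_amp = 0.3, drift_freq = 0.1,
                        subject_jitter = 0.15, fs = 100, duration = 620,
                        seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(sigma)) {
    sigma <- if (preset == "easy") {
      c(H = 0.6, M = 1.0, N = 1.6)
    } else {
      # "hard": adjacent levels differ by ~4/3 in sigma.  A 2 s window spans
      # only ~2 OU time constants, so its variance estimate is very noisy;
      # this spread keeps single-window classification well below ceiling
      # while staying clearly learnable (much narrower spreads collapse to
      # chance for every classifier, window variance being the only signal).
      c(H = 0.75, M = 1.0, N = 1.33)
    }
  }
  stopifnot(theta > 0, fs > 0, duration > 0, subject_jitter >= 0,
            drift_amp >= 0, drift_freq >= 0)
  sigma <- sigma[BALANCE_LEVELS]
  if (anyNA(sigma)) stop("sigma must be named with levels H, M, N")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (any(sigma > 0) && !(sigma[["H"]] < sigma[["M"]] &&
                          sigma[["M"]] < sigma[["N"]])) {
    stop("sigma must be strictly increasing H < M < N ",
         "(smaller sway = better balance)")
  }
  structure(list(preset = preset, theta = theta, sigma = sigma,
                 drift_amp = drift_amp, drift_freq = drift_freq,
                 subject_jitter = subject_jitter, fs = fs,
                 duration = duration, seed = as.integer(seed)),
            class = "sway_params")
}

#' Simulate one subject's COP recording
#'
#' Each channel follows the Euler-Maruyama discretization
#' `c[t+1] = c[t] - theta * c[t] * dt + sigma_eff * sqrt(dt) * eps[t]`
#' with `c[1] = 0` and `dt = 1/fs`, plus an additive drift
#' `drift_amp * sin(2 * pi * drift_freq * t + phi)` with a per-channel
#' seeded phase.  `sigma_eff` applies the per-subject jitter.  The series
#' is bit-reproducible from `(params$seed, level, subject_index)`.
#'
#' @param params A [sway_params()].
#' @param level `"H"`, `"M"`, or `"N"`.
#' @param subject_index Positive integer (1, 2, ... within the level).
#' @return A [cop_recording()] with subject id like `"H#1"`.
#' @export
simulate_subject <- function(params, level, subject_index = 1L) {
  stopifnot(inherits(params, "sway_params"))
  level <- match.arg(level, BALANCE_LEVELS)
  sid <- sprintf("%s#%d", level, subject_index)
  n_steps <- round(params$duration * params$fs)
  dt <- 1 / params$fs
  a <- 1 - params$theta * dt
  chans <- with_seed(derive_seed(params$seed, paste0("sway-", sid)), {
    u <- runif(1, -1, 1)
    sigma_eff <- params$sigma[[level]] * (1 + params$subject_jitter * u)
    lapply(1:2, function(ch) {
      phi <- runif(1, 0, 2 * pi)
      eps <- rnorm(n_steps - 1L)
      ou <- c(0, stats::filter(sigma_eff * sqrt(dt) * eps, a,
                               method = "recursive"))
      tt <- (seq_len(n_steps) - 1) * dt
      as.numeric(ou) +
        params$drift_amp * sin(2 * pi * params$drift_freq * tt + phi)
    })
  })
  cop_recording(sid, level, chans[[1L]], chans[[2L]], params$fs)
}

#' Simulate the full six-subject dataset
#'
#' Two subjects per level (H#1, H#2, M#1, M#2, N#1, N#2), each long enough
#' to supply any standard task at the default windowing.
#'
#' @param params A [sway_params()].
#' @return List with `recordings` (named list of [cop_recording()]) and
#'   `manifest` (data frame with columns `subject_id`, `level`, `path`,
#'   `fs`; `path` is `NA` until the recordings are written to disk).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sway_params"))
  grid <- expand.grid(idx = 1:2, level = BALANCE_LEVELS,
                      stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(grid)), function(i) {
    simulate_subject(params, grid$level[i], grid$idx[i])
  })
  names(recordings) <- vapply(recordings, `[[`, character(1), "subject_id")
  manifest <- data.frame(subject_id = names(recordings),
                         level = grid$level,
                         path = NA_character_,
                         fs = params$fs,
                         stringsAsFactors = FALSE)
  list(recordings = recordings, manifest = manifest, params = params)
}
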