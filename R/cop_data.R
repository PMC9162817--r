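# Data model and I/O for center-of-pressure (COP) recordings: parsing,
# windowing into fixed-size samples, and assembly of train/test tasks.

BALANCE_LEVELS <- c("H", "M", "N")

#' Construct a COP recording
#'
#' One subject's two-channel stabilometric time series: anteroposterior (`x`)
#' and mediolateral (`y`) displacement sampled at `fs` Hz, with a balance
#' level label: `"H"` (high-level athlete), `"M"` (medium-level athlete), or
#' `"N"` (normal person).
#'
#' @param subject_id Subject code, e.g. `"H#1"`.
#' @param level One of `"H"`, `"M"`, `"N"`.
#' @param x,y Numeric series of equal length; all values finite.
#' @param fs Sampling rate in Hz (default 100).
#' @return An object of class `cop_recording`.
#' @export
cop_recording <- function(subject_id, level, x, y, fs = 100) {
  level <- match.arg(level, BALANCE_LEVELS)
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("channel lengths differ: len(x) = ", length(x),
         ", len(y) = ", length(y))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("recording contains non-finite values")
  }
  structure(list(subject_id = subject_id, level = level, fs = fs,
                 x = x, y = y),
            class = "cop_recording")
}

#' @export
print.cop_recording <- function(x, ...) {
  cat(sprintf("<cop_recording %s level=%s fs=%g Hz T=%d (%.1f s)>\n",
              x$subject_id, x$level, x$fs, length(x$x),
              length(x$x) / x$fs))
  invisible(x)
}

#' Map balance levels to 0-based class labels
#'
#' The fixed encoding used throughout the package: H -> 0, M -> 1, N -> 2.
#'
#' @param level Character vector of levels.
#' @return Integer labels.
#' @export
level_to_label <- function(level) {
  lab <- match(level, BALANCE_LEVELS) - 1L
  if (anyNA(lab)) stop("unknown level(s): ", paste(level[is.na(lab)], collapse = ", "))
  lab
}

#' Read a COP recording from delimited text
#'
#' Accepts comma- or tab-separated files with header `t,x,y` or `x,y`
#' (a leading time column, if present, is dropped; timing is carried by
#' `fs`).  Malformed rows and non-finite cells raise errors that name the
#' offending line.
#'
#' @param path File path.
#' @param subject_id,level,fs Passed to [cop_recording()]; `fs` normally
#'   comes from the dataset manifest.
#' @return A [cop_recording()].
#' @export
read_recording <- function(path, subject_id, level, fs = 100) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("file ", path, " is empty or has no data rows")
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  header <- trimws(tolower(strsplit(lines[1L], sep, fixed = TRUE)[[1L]]))
  if (identical(header, c("t", "x", "y"))) {
    cols <- 2:3
  } else if (identical(header, c("x", "y"))) {
    cols <- 1:2
  } else {
    stop("unrecognized header in ", path, ": expected 't,x,y' or 'x,y', got '",
         lines[1L], "'")
  }
  n_fields <- length(header)
  body <- strsplit(lines[-1L], sep, fixed = TRUE)
  len <- lengths(body)
  if (any(len != n_fields)) {
    bad <- which(len != n_fields)[1L]
    stop("line ", bad + 1L, " of ", path, " has ", len[bad],
         " fields, expected ", n_fields)
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[cols]), numeric(2))
  )
  if (!all(is.finite(vals))) {
    bad <- which(!apply(is.finite(vals), 2L, all))[1L]
    stop("non-numeric or non-finite value on line ", bad + 1L, " of ", path)
  }
  cop_recording(subject_id, level, vals[1L, ], vals[2L, ], fs)
}

#' Write a COP recording as CSV
#'
#' Inverse of [read_recording()]: writes header `t,x,y` with the time column
#' reconstructed from `fs`.
#'
#' @param rec A [cop_recording()].
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "cop_recording"))
  df <- data.frame(t = (seq_along(rec$x) - 1) / rec$fs, x = rec$x, y = rec$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a sample set
#'
#' A stack of fixed-length two-channel windows with 0-based class labels and
#' per-sample subject provenance.  Samples are stored as an array of
#' dimension `[2, n_in, n]` (channel, time, sample).
#'
#' @param samples Numeric array `[2, n_in, n]`.
#' @param labels Integer labels in `{0, 1, 2}` (see [level_to_label()]).
#' @param subject_ids Character vector of length `n`.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(samples, labels, subject_ids) {
  stopifnot(is.array(samples), length(dim(samples)) == 3L,
            dim(samples)[1L] == 2L)
  n <- dim(samples)[3L]
  labels <- as.integer(labels)
  if (length(labels) != n || length(subject_ids) != n) {
    stop("labels/subject_ids length must match sample count ", n)
  }
  if (!all(labels %in% 0:2)) stop("labels must be in {0, 1, 2}")
  structure(list(samples = samples, labels = labels,
                 subject_ids = as.character(subject_ids),
                 n_in = dim(samples)[2L]),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set n=%d, window=[2 x %d], classes: %s>\n",
              n_samples(x), x$n_in,
              paste(sprintf("%s=%d", BALANCE_LEVELS,
                            tabulate(x$labels + 1L, 3L)), collapse = " ")))
  invisible(x)
}

#' Number of samples in a sample set
#' @param s A [sample_set()].
#' @export
n_samples <- function(s) dim(s$samples)[3L]

subset_samples <- function(s, idx) {
  sample_set(s$samples[, , idx, drop = FALSE], s$labels[idx],
             s$subject_ids[idx])
}

bind_sample_sets <- function(sets) {
  samples <- array(unlist(lapply(sets, `[[`, "samples")),
                   dim = c(2L, sets[[1L]]$n_in,
                           sum(vapply(sets, n_samples, integer(1)))))
  sample_set(samples,
             unlist(lapply(sets, `[[`, "labels")),
             unlist(lapply(sets, `[[`, "subject_ids")))
}

#' Slice a recording into fixed-length windows
#'
#' Window `i` (1-based) covers time steps `[(i-1)*stride + 1,
#' (i-1)*stride + n_in]`; the number of windows is
#' `floor((T - n_in)/stride) + 1`.  Every window inherits the recording's
#' level label.
#'
#' @param rec A [cop_recording()].
#' @param n_in Window length in time steps (the model input length).
#' @param stride Step between consecutive window starts (`>= 1`).
#' @return A [sample_set()].
#' @export
window_recording <- function(rec, n_in, stride = n_in %/% 2L) {
  stopifnot(inherits(rec, "cop_recording"), n_in >= 1L, stride >= 1L)
  T <- length(rec$x)
  if (n_in > T) {
    stop("insufficient data: window length ", n_in,
         " exceeds recording length ", T)
  }
  starts <- seq.int(1L, T - n_in + 1L, by = stride)
  samples <- array(0, dim = c(2L, n_in, length(starts)))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + n_in - 1L)
    samples[1L, , i] <- rec$x[idx]
    samples[2L, , i] <- rec$y[idx]
  }
  sample_set(samples, rep(level_to_label(rec$level), length(starts)),
             rep(rec$subject_id, length(starts)))
}

#' Define an evaluation task
#'
#' A task names one subject per balance level and the number of training and
#' testing samples to draw, balanced across the three subjects.
#'
#' @param name Task name, e.g. `"T1"`.
#' @param subjects Character vector of three subject ids whose first letter
#'   is the level, exactly one per level (e.g. `c("H#1", "M#1", "N#1")`).
#' @param n_train,n_test Total sample counts (each divisible by 3).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(name, subjects, n_train = 1200L, n_test = 600L) {
  stopifnot(length(subjects) == 3L, n_train > 0L, n_test > 0L)
  levels <- substr(subjects, 1L, 1L)
  if (!setequal(levels, BALANCE_LEVELS)) {
    stop("task must name exactly one subject per level H/M/N, got: ",
         paste(subjects, collapse = ", "))
  }
  if (n_train %% 3L != 0L || n_test %% 3L != 0L) {
    stop("n_train and n_test must be divisible by 3 for class balance")
  }
  structure(list(name = name, subjects = subjects[order(levels)],
                 n_train = as.integer(n_train), n_test = as.integer(n_test)),
            class = "task_spec")
}

#' The four standard evaluation tasks
#'
#' Tasks T1-T4 pair the six subjects (two per level) into four
#' train/test settings of 1200 training and 600 testing samples each.
#'
#' @return Named list of [task_spec()] objects.
#' @export
cop_tasks <- function() {
  list(
    T1 = task_spec("T1", c("H#1", "M#1", "N#1")),
    T2 = task_spec("T2", c("H#2", "M#2", "N#2")),
    T3 = task_spec("T3", c("H#1", "M#2", "N#1")),
    T4 = task_spec("T4", c("H#2", "M#1", "N#2"))
  )
}

#' Assemble a task's training and testing sample sets
#'
#' Each subject's recording is windowed, the earliest windows go to
#' training and the latest to testing, and enough intermediate windows are
#' left unused that no time step is shared between a training and a testing
#' window of the same subject (overlapping windows would otherwise leak).
#' The pooled sets are then shuffled reproducibly.
#'
#' @param task A [task_spec()].
#' @param recordings Named list of [cop_recording()] (names = subject ids),
#'   or the `recordings` element of [simulate_dataset()] output.
#' @param n_in Window length (default 200 time steps).
#' @param stride Window stride (default `n_in/2`, i.e. 50% overlap).
#' @param seed Integer seed for the shuffles.
#' @return List with elements `train` and `test`, both [sample_set()]s,
#'   class-balanced (`n_train/3` and `n_test/3` per subject).
#' @export
build_task <- function(task, recordings, n_in = 200L, stride = n_in %/% 2L,
                       seed = 1L) {
  stopifnot(inherits(task, "task_spec"))
  if (!is.null(recordings$recordings)) recordings <- recordings$recordings
  missing <- setdiff(task$subjects, names(recordings))
  if (length(missing) > 0L) {
    stop("recordings missing for subject(s): ", paste(missing, collapse = ", "))
  }
  k <- task$n_train %/% 3L
  m <- task$n_test %/% 3L
  train_parts <- list()
  test_parts <- list()
  for (sid in task$subjects) {
    ss <- window_recording(recordings[[sid]], n_in, stride)
    w <- n_samples(ss)
    # leakage guard: last training window must end before the first testing
    # window starts
    gap_ok <- w >= k + m && (w - m) * stride >= (k - 1L) * stride + n_in
    if (!gap_ok) {
      need <- k + m + ceiling(n_in / stride) - 1L
      stop("insufficient data for subject ", sid, ": need >= ", need,
           " windows (", k, " train + ", m, " test + leakage gap), have ", w)
    }
    train_parts[[sid]] <- subset_samples(ss, seq_len(k))
    test_parts[[sid]] <- subset_samples(ss, (w - m + 1L):w)
  }
  train <- bind_sample_sets(train_parts)
  test <- bind_sample_sets(test_parts)
  with_seed(derive_seed(seed, paste0("split-", task$name)), {
    train <- subset_samples(train, sample.int(n_samples(train)))
    test <- subset_samples(test, sample.int(n_samples(test)))
  })
  list(train = train, test = test)
}

#' Z-score sample sets using training statistics
#'
#' Per-channel mean and standard deviation (population form, i.e. divisor
#' `n`) are computed on the training set only and applied to both sets; a
#' zero standard deviation is replaced by one so constant channels pass
#' through unchanged.
#'
#' @param train,test [sample_set()]s.
#' @return List `(train, test, stats)` where `stats` holds the per-channel
#'   `mean` and `sd` used.
#' @export
standardize <- function(train, test) {
  stopifnot(n_samples(train) > 0L)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mu <- c(mean(train$samples[1L, , ]), mean(train$samples[2L, , ]))
  sigma <- c(pop_sd(as.vector(train$samples[1L, , ])),
             pop_sd(as.vector(train$samples[2L, , ])))
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  scale_set <- function(s) {
    for (ch in 1:2) {
      s$samples[ch, , ] <- (s$samples[ch, , ] - mu[ch]) / sigma[ch]
    }
    s
  }
  list(train = scale_set(train), test = scale_set(test),
       stats = list(mean = mu, sd = sigma))
}
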