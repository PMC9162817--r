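# Recording I/O, windowing arithmetic, task assembly hygiene and
# standardization.

test_that("read_recording parses t,x,y and x,y files and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y", "0,1.0,2.0", "0.01,1.1,2.1", "0.02,1.2,2.2"), path)
  rec <- read_recording(path, "H#1", "H")
  expect_length(rec$x, 3)
  expect_equal(rec$x, c(1.0, 1.1, 1.2))
  expect_equal(rec$y, c(2.0, 2.1, 2.2))

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,4", "2,5"), path2)
  rec2 <- read_recording(path2, "M#1", "M")
  expect_equal(rec2$y, c(4, 5))

  # write -> read identity on values
  rec3 <- toy_recording("N#1", n = 50L)
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec3, path3)
  back <- read_recording(path3, rec3$subject_id, rec3$level, rec3$fs)
  expect_equal(back$x, rec3$x, tolerance = 1e-9)
  expect_equal(back$y, rec3$y, tolerance = 1e-9)
})

test_that("read_recording rejects malformed input with line numbers", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_recording(empty, "H#1", "H"), "empty")

  bad_nan <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "NaN,3"), bad_nan)
  expect_error(read_recording(bad_nan, "H#1", "H"), "line 3")

  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y", "0,1,2", "0.01,1"), ragged)
  expect_error(read_recording(ragged, "H#1", "H"), "line 3")
})

test_that("cop_recording enforces its invariants", {
  expect_error(cop_recording("H#1", "H", 1:3, 1:2), "lengths differ")
  expect_error(cop_recording("H#1", "H", c(1, NA), c(1, 2)), "non-finite")
  expect_error(cop_recording("H#1", "X", 1:2, 1:2))
  expect_equal(level_to_label(c("H", "M", "N")), c(0L, 1L, 2L))
  expect_error(level_to_label("Z"), "unknown level")
})

test_that("window count follows floor((T - n_in)/stride) + 1 exactly", {
  rec <- toy_recording("H#1", n = 2200L)
  expect_equal(n_samples(window_recording(rec, 200L, 100L)), 21L)

  short <- toy_recording("H#1", n = 200L)
  one <- window_recording(short, 200L, 1L)
  expect_equal(n_samples(one), 1L)
  expect_equal(one$samples[1, , 1], short$x)

  expect_error(window_recording(toy_recording("H#1", n = 199L), 200L),
               "insufficient data")

  # property: formula vs direct enumeration over many (T, n_in, stride)
  set.seed(11)
  for (rep in 1:30) {
    T <- sample(30:200, 1)
    n_in <- sample(5:T, 1)
    stride <- sample(1:20, 1)
    r <- toy_recording("M#1", n = T, seed = rep)
    enumerated <- length(seq(1, T - n_in + 1, by = stride))
    expect_equal(n_samples(window_recording(r, n_in, stride)),
                 floor((T - n_in) / stride) + 1)
    expect_equal(floor((T - n_in) / stride) + 1, enumerated)
  }
})

test_that("windows carry the recording's label and correct content", {
  rec <- toy_recording("N#2", n = 60L)
  ss <- window_recording(rec, 20L, 10L)
  expect_true(all(ss$labels == 2L))
  expect_true(all(ss$subject_ids == "N#2"))
  expect_equal(ss$samples[2, , 3], rec$y[21:40])  # window 3 starts at 21
})

test_that("build_task emits balanced leak-free splits deterministically", {
  recs <- list(`H#1` = toy_recording("H#1", n = 400L),
               `M#1` = toy_recording("M#1", n = 400L),
               `N#1` = toy_recording("N#1", n = 400L))
  task <- task_spec("toy", c("H#1", "M#1", "N#1"),
                    n_train = 9L, n_test = 6L)
  split <- build_task(task, recs, n_in = 50L, stride = 25L, seed = 3)
  expect_equal(n_samples(split$train), 9L)
  expect_equal(n_samples(split$test), 6L)
  expect_equal(tabulate(split$train$labels + 1L, 3L), rep(3L, 3))
  expect_equal(tabulate(split$test$labels + 1L, 3L), rep(2L, 3))

  # determinism: same seed, identical ordering
  split2 <- build_task(task, recs, n_in = 50L, stride = 25L, seed = 3)
  expect_identical(split$train$samples, split2$train$samples)
  expect_identical(split$test$subject_ids, split2$test$subject_ids)

  # leakage: reconstruct per-subject time-step coverage exhaustively; the
  # train windows are the earliest, so every train step must precede every
  # test step for the same subject
  for (sid in task$subjects) {
    rec <- recs[[sid]]
    locate <- function(s) {
      # windows are contiguous slices; find the start by matching
      for (st in seq(1, length(rec$x) - 50 + 1)) {
        if (all(rec$x[st:(st + 49)] == s)) return(st:(st + 49))
      }
      stop("window not found")
    }
    train_steps <- unlist(lapply(which(split$train$subject_ids == sid),
                                 function(i) locate(split$train$samples[1, , i])))
    test_steps <- unlist(lapply(which(split$test$subject_ids == sid),
                                function(i) locate(split$test$samples[1, , i])))
    expect_length(intersect(train_steps, test_steps), 0)
    expect_true(max(train_steps) < min(test_steps))
  }
})

test_that("build_task reports insufficient data with counts", {
  recs <- list(`H#1` = toy_recording("H#1", n = 100L),
               `M#1` = toy_recording("M#1", n = 100L),
               `N#1` = toy_recording("N#1", n = 100L))
  task <- task_spec("toy", c("H#1", "M#1", "N#1"),
                    n_train = 30L, n_test = 30L)
  expect_error(build_task(task, recs, n_in = 50L, stride = 25L),
               "insufficient data.*need.*have")
})

test_that("chronological minimal split puts train strictly before test", {
  # three subjects, exactly 1 train + 1 test window each with a gap
  recs <- list(`H#1` = toy_recording("H#1", n = 90L),
               `M#1` = toy_recording("M#1", n = 90L),
               `N#1` = toy_recording("N#1", n = 90L))
  task <- task_spec("tiny", c("H#1", "M#1", "N#1"),
                    n_train = 3L, n_test = 3L)
  split <- build_task(task, recs, n_in = 30L, stride = 30L, seed = 1)
  for (sid in task$subjects) {
    tr <- split$train$samples[1, , split$train$subject_ids == sid]
    te <- split$test$samples[1, , split$test$subject_ids == sid]
    expect_equal(tr, recs[[sid]]$x[1:30])    # earliest window
    expect_equal(te, recs[[sid]]$x[61:90])   # latest window
  }
})

test_that("standardize uses train moments only and guards zero sd", {
  tr <- toy_sample_set(n = 30L)
  te <- toy_sample_set(n = 12L, seed = 2)
  te$samples <- te$samples + 5   # shifted test set
  z <- standardize(tr, te)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  for (ch in 1:2) {
    expect_equal(mean(z$train$samples[ch, , ]), 0, tolerance = 1e-9)
    expect_equal(pop_sd(as.vector(z$train$samples[ch, , ])), 1,
                 tolerance = 1e-9)
  }
  # the test set is transformed with TRAIN statistics, so its mean shifts
  expect_gt(mean(z$test$samples[1, , ]), 2)

  # constant channel passes through unchanged
  const <- tr
  const$samples[1, , ] <- 3
  z2 <- standardize(const, te)
  expect_true(all(z2$train$samples[1, , ] == 0))
  expect_equal(z2$stats$sd[1], 1)

  # two-point closed form: values {1, 3} -> mean 2, sd 1 -> {-1, +1}
  two <- sample_set(array(c(1, 1, 3, 3), c(2, 1, 2)), c(0L, 1L),
                    c("H#1", "M#1"))
  z3 <- standardize(two, two)
  expect_equal(z3$stats$mean, c(2, 2))
  expect_equal(z3$stats$sd, c(1, 1))
  expect_equal(sort(unique(as.vector(z3$train$samples))), c(-1, 1))
})
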