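test_that("count_spikes uses a half-open window", {
  mt <- count_window(0.03, 0.2)
  expect_identical(count_spikes(c(0.05, 0.10, 0.25), mt), 2L)
  expect_identical(count_spikes(numeric(0), mt), 0L)
  # start included, end excluded
  expect_identical(count_spikes(c(0.03, 0.2299), mt), 2L)
  expect_identical(count_spikes(c(0.23), mt), 0L)
  expect_error(count_spikes(c(0.1, NaN), mt), "finite")
})

test_that("window presets resolve to the documented values", {
  mt <- window_preset("MT"); it <- window_preset("IT")
  itl <- window_preset("IT_long")
  expect_equal(c(mt$latency_offset, mt$duration), c(0.030, 0.200))
  expect_equal(c(it$latency_offset, it$duration), c(0.050, 0.200))
  expect_equal(c(itl$latency_offset, itl$duration), c(0.050, 0.400))
  # count -> Hz conversion factor for the 200 ms window
  expect_equal(1 / mt$duration, 5)
  expect_error(count_window(0.03, 0), "duration")
  expect_error(count_window(-0.1, 0.2), "latency_offset")
})

test_that("counting is order-invariant and matches a brute-force scan", {
  set.seed(41)
  w <- count_window(0.03, 0.2)
  for (i in 1:25) {
    times <- round(stats::runif(sample(0:30, 1), 0, 0.4), 3)
    expect_identical(count_spikes(times, w),
                     oracle_count(times, 0.03, 0.23))
    expect_identical(count_spikes(sample(times), w), count_spikes(times, w))
  }
})

test_that("microsaccade detection thresholds on fixation statistics", {
  # constant trace: sd = 0, threshold = mean, strict rule flags nothing
  expect_length(detect_microsaccades(rep(1, 100), 1:50, 51:100), 0)
  # hand-built trace: fixation mean 1, sd 0.5; threshold = 1 + 6*0.5 = 4
  fix <- rep(c(0.5, 1.5), 25)            # mean 1, sd ~0.5 (n-1)
  sd_fix <- stats::sd(fix)
  thr <- mean(fix) + 6 * sd_fix
  stim <- rep(1, 40); stim[17] <- thr + 0.5
  ms <- detect_microsaccades(c(fix, stim), 1:50, 51:90)
  expect_length(ms, 1)
  expect_equal(ms[[1]], c(67, 67))       # single-sample run at index 50+17
  # a sample exactly at threshold is not "more than" the threshold
  stim[17] <- thr
  expect_length(detect_microsaccades(c(fix, stim), 1:50, 51:90), 0)
  expect_error(detect_microsaccades(rep(1, 10), integer(0), 1:10), "empty")
})

test_that("microsaccade runs are maximal contiguous ranges", {
  fix <- c(rep(0.9, 20), rep(1.1, 20))   # mean 1
  stim <- rep(1, 20)
  stim[c(3, 4, 5, 10, 15, 16)] <- 100
  ms <- detect_microsaccades(c(fix, stim), 1:40, 41:60)
  expect_length(ms, 3)
  expect_equal(ms[[1]], c(43, 45))
  expect_equal(ms[[2]], c(50, 50))
  expect_equal(ms[[3]], c(55, 56))
})

make_trial_df <- function(n_a = 5, n_b = 5, n_ab = 5, unit = "u1",
                          sa = "s1", sb = "s2", correct = TRUE) {
  n <- n_a + n_b + n_ab
  data.frame(unit_id = unit,
             trial_id = sprintf("%s_%s_t%02d", unit, sa, seq_len(n)),
             condition = rep(c("A", "B", "AB"), c(n_a, n_b, n_ab)),
             stimulus_a_id = sa, stimulus_b_id = sb,
             correct = correct,
             spike_count = rep(c(20L, 5L, 12L), c(n_a, n_b, n_ab)),
             stringsAsFactors = FALSE)
}

test_that("build_triplets assembles, filters and groups", {
  df <- make_trial_df()
  tps <- build_triplets(df)
  expect_length(tps, 1)
  expect_length(tps[[1]]$a_counts, 5)
  expect_length(tps[[1]]$ab_counts, 5)

  # one incorrect AB trial is dropped
  df2 <- df; df2$correct[11] <- FALSE
  expect_length(build_triplets(df2)[[1]]$ab_counts, 4)

  # two stimulus pairs for one unit give two triplets
  df3 <- rbind(df, make_trial_df(sa = "s1", sb = "s3"))
  expect_length(build_triplets(df3), 2)

  # unresolvable condition labels are skipped with a warning
  df4 <- df; df4$condition[1] <- "C"
  expect_warning(tps4 <- build_triplets(df4), "unresolvable")
  expect_length(tps4[[1]]$a_counts, 4)
})

test_that("build_triplets output is invariant to trial order", {
  df <- make_trial_df()
  df$spike_count <- seq_len(nrow(df))  # distinguishable counts
  t1 <- build_triplets(df)[[1]]
  t2 <- build_triplets(df[sample(nrow(df)), ])[[1]]
  expect_identical(t1$a_counts, t2$a_counts)
  expect_identical(t1$ab_counts, t2$ab_counts)
})

test_that("counts come from timestamps when no spike_count is given", {
  df <- make_trial_df(n_a = 1, n_b = 1, n_ab = 1)
  df$spike_count <- NULL
  # two spikes inside [0.03, 0.23), one outside
  df$spike_times <- c("0.05;0.10;0.30", "0.04", "0.05;0.229;0.231")
  tps <- build_triplets(df, window_preset("MT"))
  expect_identical(tps[[1]]$a_counts, 2L)
  expect_identical(tps[[1]]$b_counts, 1L)
  expect_identical(tps[[1]]$ab_counts, 2L)
  # neither counts nor timestamps is an input error
  df$spike_times[2] <- NA
  expect_error(build_triplets(df), "neither")
})

test_that("trial CSV round-trips and eye traces gate trials", {
  df <- make_trial_df()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(df, path)
  back <- read_trials(path)
  expect_equal(back$spike_count, df$spike_count)
  expect_equal(back$condition, df$condition)

  # companion eye file: one AB trial gets a microsaccade, others clean
  eye_path <- withr::local_tempfile(fileext = ".csv")
  speeds_clean <- paste(rep(1, 60), collapse = ";")
  bad <- rep(1, 60); bad[45] <- 50
  eye <- data.frame(trial_id = df$trial_id[c(1, 11)],
                    speeds = c(speeds_clean, paste(bad, collapse = ";")),
                    fix_start = 1, fix_end = 30,
                    stim_start = 31, stim_end = 60)
  utils::write.csv(eye, eye_path, row.names = FALSE, quote = FALSE)
  withced <- read_trials(path, eye_path)
  tps <- build_triplets(withced)
  expect_length(tps[[1]]$ab_counts, 4)  # the flagged AB trial dropped
  expect_length(tps[[1]]$a_counts, 5)   # clean trace retained
})
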