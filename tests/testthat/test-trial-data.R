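# Trial-table IO, validation and descriptive summaries.

test_that("write/read round-trips a dataset exactly", {
  sim <- simulate_dataset("precision_change_dynamic", n_subjects = 2,
                          p_timeout = 0.05, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(sim, path)
  back <- read_trials(path)
  orig <- tibble::as_tibble(sim)[trial_columns()]
  attributes(orig) <- attributes(orig)[c("names", "row.names", "class")]
  class(orig) <- class(back)
  orig$session <- as.integer(orig$session)
  orig$run <- as.integer(orig$run)
  orig$trial <- as.integer(orig$trial)
  expect_equal(back, orig, tolerance = 1e-12)
  expect_true(anyNA(back$rating)) # timeouts preserved as missing
})

test_that("an empty dataset writes a header-only file", {
  d <- make_subject()[0, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(d, path)
  expect_length(readLines(path), 1)
  one <- make_subject()[1, ]
  write_trials(one, path)
  expect_length(readLines(path), 2)
})

test_that("validation catches out-of-range and schedule breaches", {
  d <- make_subject()
  d$rating[3] <- 101
  expect_error(validate_trials(d), "rating out of \\[0,100\\]")
  expect_warning(validate_trials(d, strict = FALSE), "rating out of")

  d2 <- make_subject()
  d2$intensity_level[d2$run == 1] <- 50 # breaks 5-per-level
  expect_error(validate_trials(d2), "5 trials per intensity")

  d3 <- make_subject()
  d3$condition[1] <- "P" # run no longer single-condition
  expect_error(validate_trials(d3), "constant within a run")

  # partial designs only warn
  expect_warning(validate_trials(make_subject()[1:15, ]), "Incomplete")
})

test_that("malformed TSV rows raise a parse error naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(make_subject(), path)
  lines <- readLines(path)
  lines[5] <- gsub("\t1\t", "\tnot_a_number\t", lines[5])
  writeLines(lines, path)
  expect_error(suppressWarnings(read_trials(path)), "line|row|Malformed")
})

test_that("within-subject SDs use the n-1 denominator per cell", {
  d <- make_subject(rating_fun = function(r) rep(50, nrow(r)))
  tab <- within_subject_sd_table(d)
  expect_true(all(tab$sd == 0))
  expect_true(all(tab$n == 10))

  # hand-computed two-value cell: sd({40, 60}) = sqrt(200) ~ 14.142
  d2 <- make_run("A", 1, "C", 1)
  d2$rating[d2$intensity_level == 30] <- c(40, 60, NA, NA, NA)
  tab2 <- within_subject_sd_table(d2)
  row <- tab2[tab2$intensity_level == 30, ]
  expect_equal(row$sd, sqrt(200), tolerance = 1e-9)
  expect_equal(row$n, 2L)

  # single observed rating: sd undefined, n = 1
  d3 <- make_run("A", 1, "C", 1)
  d3$rating[d3$intensity_level == 50] <- c(55, NA, NA, NA, NA)
  row3 <- within_subject_sd_table(d3)
  expect_true(is.na(row3$sd[row3$intensity_level == 50]))
  expect_equal(row3$n[row3$intensity_level == 50], 1L)
})

test_that("within-subject SDs are shift-invariant and scale linearly", {
  sim <- simulate_dataset(n_subjects = 2, seed = 3)
  base <- within_subject_sd_table(sim)
  shifted <- sim
  shifted$rating <- shifted$rating + 5 # no clipping applied here
  expect_equal(within_subject_sd_table(shifted)$sd, base$sd,
               tolerance = 1e-9)
  scaled <- sim
  scaled$rating <- scaled$rating * 0.5
  expect_equal(within_subject_sd_table(scaled)$sd, base$sd * 0.5,
               tolerance = 1e-9)
})

test_that("choice percentages sum to 100 at each trial position", {
  # all subjects choose 70 at trial 1
  d <- dplyr::bind_rows(
    make_run("A", 1, "C", 1, levels = c(70, 70, 70, 70, 70,
                                        50, 50, 50, 50, 50,
                                        30, 30, 30, 30, 30)),
    make_run("B", 1, "C", 1, levels = c(70, 30, 50, 70, 70,
                                        50, 50, 50, 30, 30,
                                        70, 70, 30, 30, 50)))
  cp <- choice_percentages(d)
  expect_equal(cp$percent[cp$trial == 1 & cp$intensity_level == 70], 100)
  expect_equal(cp$percent[cp$trial == 1 & cp$intensity_level == 30], 0)
  # split choice at trial 2: 70 vs 30 -> 50/50/0
  expect_equal(sort(cp$percent[cp$trial == 2]), c(0, 50, 50))

  sums <- cp |>
    dplyr::group_by(trial) |>
    dplyr::summarise(s = sum(percent))
  expect_true(all(abs(sums$s - 100) < 1e-9))

  # no controllable trials -> empty table
  expect_equal(nrow(choice_percentages(make_run("A", 1, "U", 1))), 0)
})

test_that("reaction-time summaries are plain means and SDs", {
  d <- make_subject()
  s <- rt_summary(d)
  expect_equal(s$mean_rt, rep(1, 3))
  expect_equal(s$sd_rt, rep(0, 3))

  d$reaction_time[d$condition == "C"] <- rep(c(1, 2), length.out = 30)
  s2 <- rt_summary(d)
  expect_equal(s2$mean_rt[s2$condition == "C"], 1.5)

  # generator contract: choices are slower than colour matching
  sim <- simulate_dataset(n_subjects = 10, seed = 5)
  s3 <- rt_summary(sim)
  expect_gt(s3$mean_rt[s3$condition == "C"],
            s3$mean_rt[s3$condition == "P"])
})
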