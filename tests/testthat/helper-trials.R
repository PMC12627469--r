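# Build small valid trial tables in code (no fixtures on disk).

# one valid run: 15 trials, 5 per level, fixed or supplied sequence
make_run <- function(subject_id, run, condition, session,
                     levels = rep(c(30, 50, 70), 5),
                     rating = NULL, reaction_time = 1, chosen = NULL) {
  tibble::tibble(
    subject_id = subject_id, session = as.integer(session),
    run = as.integer(run), trial = 1:15, condition = condition,
    intensity_level = as.numeric(levels),
    rating = if (is.null(rating)) as.numeric(levels) else rating,
    reaction_time = reaction_time,
    chosen = if (is.null(chosen)) condition == "C" else chosen)
}

# one subject with the full 6-run design
make_subject <- function(subject_id = "S1", rating_fun = NULL) {
  runs <- purrr::map2_dfr(
    1:6, c("C", "P", "U", "C", "P", "U"),
    function(r, cond) {
      make_run(subject_id, r, cond, session = ifelse(r <= 3, 1, 2))
    })
  if (!is.null(rating_fun)) runs$rating <- rating_fun(runs)
  runs
}

# a fast MCMC profile for tests that only need a running sampler
test_mcmc <- function(chains = 2, iter = 500, warmup = 250, adapt = 200) {
  list(chains = chains, iter = iter, warmup = warmup, adapt = adapt,
       thin = 1L)
}
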