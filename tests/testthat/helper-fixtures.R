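# small handmade fixtures, built in code

tiny_lexicon <- function(n = 8) {
  as_lexicon(data.frame(
    word = paste0("w", seq_len(n)),
    n_letters = rep(c(5, 7, 9, 11), length.out = n),
    n_syllables = rep(c(2, 3), length.out = n),
    log10_freq = seq(1, 2, length.out = n),
    valence = seq(-1.5, 1.5, length.out = n)
  ))
}

tiny_ratings <- function(lex = tiny_lexicon(),
                         self = c(70, 60, 55, 52, 48, 45, 40, 30),
                         other = c(30, 40, 45, 48, 52, 55, 60, 70)) {
  as_standard_ratings(data.frame(word = lex$word,
                                 self_rating = self[seq_len(nrow(lex))],
                                 other_rating = other[seq_len(nrow(lex))]),
                      lex)
}

# assemble a trial_log directly (no session), for analysis-layer tests
make_log <- function(condition, choice, confidence,
                     selfs, others, expected_self = 50,
                     expected_other = 50, participant_id = "p1") {
  n <- length(condition)
  log <- data.frame(participant_id = participant_id, trial = seq_len(n),
                    condition = condition, staircase_pos = 0,
                    center_self = 50, center_other = 50,
                    expected_self = expected_self,
                    expected_other = expected_other,
                    stringsAsFactors = FALSE)
  for (j in 1:4) log[[paste0("word_", j)]] <- paste0("w", j)
  for (j in 1:4) log[[paste0("self_", j)]] <- selfs[, j]
  for (j in 1:4) log[[paste0("other_", j)]] <- others[, j]
  log$choice <- choice
  log$correct <- choice == condition
  log$confidence <- confidence
  class(log) <- c("trial_log", "data.frame")
  log
}

# random analysis-layer log with choices unrelated to the stimulus
random_log <- function(n, seed, participant_id = "p1") {
  set.seed(seed)
  make_log(condition = sample(c("self", "other"), n, TRUE),
           choice = sample(c("self", "other"), n, TRUE),
           confidence = runif(n, 0, 100),
           selfs = matrix(rnorm(4 * n, 50, 8), n, 4),
           others = matrix(rnorm(4 * n, 50, 8), n, 4),
           participant_id = participant_id)
}

# full simulated observer batches; cached because several tests measure
# different properties of the same study-scale simulation
.batch_cache <- new.env(parent = emptyenv())

observer_batch <- function(model, n_obs = 20, n_trials = 2000,
                           seed0 = if (model == "balanced") 1000L else 2000L) {
  key <- paste(model, n_obs, n_trials, seed0, sep = "_")
  if (!is.null(.batch_cache[[key]])) return(.batch_cache[[key]])
  logs <- do.call(rbind, lapply(seq_len(n_obs), function(i) {
    lex <- generate_fixture_lexicon(104, seed = seed0 + i)
    par <- observer_params(confidence_model = model)
    rat <- generate_standard_ratings(lex, par, seed = seed0 + 500L + i)
    run_session(lex, rat, par,
                session_config(n_trials = n_trials, seed = seed0 + 1000L + i),
                participant_id = sprintf("p%02d", i))
  }))
  .batch_cache[[key]] <- logs
  logs
}

binom_ci <- function(x, n, conf = 0.95) {
  as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
}
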