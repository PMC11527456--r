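#' Session configuration
#'
#' @param n_trials total trials, split evenly across the self and other
#'   conditions (default 306; must be even).
#' @param seed integer seed governing the whole session (condition order,
#'   sampling, observer noise).
#' @param step_divisor staircase step divisor (see [init_staircase()]).
#' @param range_mode staircase range mode, `"theoretical"` or
#'   `"empirical"`.
#' @param sampler a [sampler_config()] object.
#' @param break_every trials between self-terminated breaks; logged as
#'   metadata only, no computational effect in simulation.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_trials = 306, seed = 1, step_divisor = 20,
                           range_mode = "theoretical",
                           sampler = sampler_config(), break_every = 50) {
  if (n_trials %% 2 != 0) stop("n_trials must be even (half per condition)",
                               call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 step_divisor = step_divisor, range_mode = range_mode,
                 sampler = sampler, break_every = break_every),
            class = "session_config")
}

#' Run one simulated trait-judgment session
#'
#' Runs a complete session: a seeded balanced random condition schedule,
#' one staircase per condition moving on the evidence diagonal, per-trial
#' density-corrected Gaussian word sampling at the staircase position, the
#' observer's choice and confidence, and the staircase update with the
#' trial's correctness.  Fully deterministic given `config$seed`.
#'
#' @param lexicon a [as_lexicon()] object.
#' @param ratings the participant's [as_standard_ratings()].
#' @param observer an [observer_params()] object.
#' @param config a [session_config()] object.
#' @param participant_id label written into the log.
#' @return A `trial_log` data frame, one row per trial, with the condition,
#'   staircase position, the four words with their ratings, the expected
#'   (center) coordinates, choice, correctness and confidence.
#' @export
run_session <- function(lexicon, ratings, observer = observer_params(),
                        config = session_config(),
                        participant_id = "sim01") {
  lexicon <- as_lexicon(lexicon)
  ratings <- as_standard_ratings(ratings, lexicon)
  n <- config$n_trials
  wpt <- config$sampler$words_per_trial
  if (nrow(ratings) < wpt) stop("lexicon smaller than words_per_trial",
                                call. = FALSE)
  set.seed(config$seed)
  schedule <- sample(rep(c("self", "other"), each = n / 2))

  stair <- list(
    self = init_staircase("self", ratings, config$step_divisor,
                          config$range_mode),
    other = init_staircase("other", ratings, config$step_divisor,
                           config$range_mode))
  density <- estimate_density(ratings, config$sampler$kde_bandwidth)

  sigma <- config$sampler$sigma
  if (is.null(sigma)) {
    base <- config$sampler$sigma_scale *
      abs(stair$self$position - stair$other$position)
    sigma <- c(self = base, other = base)
  } else if (length(sigma) == 1L) {
    sigma <- c(self = unname(sigma), other = unname(sigma))
  }
  if (isTRUE(config$sampler$calibrate)) {
    cal <- calibrate_sigma(
      ratings, sigma,
      starts = c(self = stair$self$position, other = stair$other$position),
      density = density, words_per_trial = wpt,
      tolerance = config$sampler$calibration_tolerance)
    sigma <- cal$sigma
  }

  condition <- character(n); staircase_pos <- numeric(n)
  center_self <- numeric(n); center_other <- numeric(n)
  expected_self <- numeric(n); expected_other <- numeric(n)
  words <- matrix(NA_character_, n, wpt)
  selfs <- matrix(NA_real_, n, wpt); others <- matrix(NA_real_, n, wpt)
  choice <- character(n); correct <- logical(n); confidence <- numeric(n)

  for (t in seq_len(n)) {
    cond <- schedule[t]
    st <- stair[[cond]]
    center <- diagonal_point(st$position)
    p <- selection_probabilities(ratings, center, sigma[[cond]], density)
    idx <- sample_trial_words(ratings, center, sigma[[cond]], density, wpt,
                              probs = p)
    s <- ratings$self_rating[idx]; o <- ratings$other_rating[idx]
    # expected ratings of a word drawn by the selection algorithm on this
    # trial; reverse correlation measures fluctuations around these
    exp_s <- sum(p * ratings$self_rating)
    exp_o <- sum(p * ratings$other_rating)
    dec <- observer_decide(s, o, observer)
    ch <- dec$choice
    ok <- ch == cond
    cf <- observer_confidence(s, o, ch, exp_s, exp_o, observer, d = dec$d)
    stair[[cond]] <- update(st, ok)

    condition[t] <- cond; staircase_pos[t] <- st$position
    center_self[t] <- center$self_coord
    center_other[t] <- center$other_coord
    expected_self[t] <- exp_s; expected_other[t] <- exp_o
    words[t, ] <- ratings$word[idx]; selfs[t, ] <- s; others[t, ] <- o
    choice[t] <- ch; correct[t] <- ok; confidence[t] <- cf
  }

  log <- data.frame(participant_id = participant_id, trial = seq_len(n),
                    condition = condition, staircase_pos = staircase_pos,
                    center_self = center_self, center_other = center_other,
                    expected_self = expected_self,
                    expected_other = expected_other,
                    stringsAsFactors = FALSE)
  colnames(words) <- paste0("word_", seq_len(wpt))
  colnames(selfs) <- paste0("self_", seq_len(wpt))
  colnames(others) <- paste0("other_", seq_len(wpt))
  log <- cbind(log, as.data.frame(words), as.data.frame(selfs),
               as.data.frame(others))
  log$choice <- choice; log$correct <- correct; log$confidence <- confidence
  attr(log, "sigma") <- sigma
  attr(log, "break_every") <- config$break_every
  class(log) <- c("trial_log", "data.frame")
  log
}

trial_log_schema <- "traitjudge_trial_log_v1"

trial_log_required_cols <- function(wpt = 4) {
  c("participant_id", "trial", "condition", "staircase_pos",
    "center_self", "center_other", "expected_self", "expected_other",
    paste0("word_", seq_len(wpt)), paste0("self_", seq_len(wpt)),
    paste0("other_", seq_len(wpt)), "choice", "correct", "confidence")
}

#' Read or write a trial log
#'
#' Trial logs are plain CSV with a schema comment line; the reader
#' validates the schema and the full column set and restores types, so a
#' written log re-reads to an identical analysis input.
#'
#' @param log a `trial_log` data frame (possibly row-bound over
#'   participants).
#' @param path file path.
#' @return `read_trial_log()` returns a `trial_log`; `write_trial_log()`
#'   returns `path` invisibly.
#' @export
write_trial_log <- function(log, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", trial_log_schema), con)
  utils::write.csv(as.data.frame(log), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!grepl(trial_log_schema, first, fixed = TRUE)) {
    stop("not a ", trial_log_schema, " file: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  wpt <- sum(grepl("^word_", names(df)))
  required <- trial_log_required_cols(wpt)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("trial log is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$correct <- as.logical(df$correct)
  class(df) <- c("trial_log", "data.frame")
  df
}

#' Words-per-trial of a trial log
#' @param log a `trial_log`.
#' @return Integer number of word positions in the log.
#' @export
words_per_trial <- function(log) {
  sum(grepl("^word_", names(log)))
}
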