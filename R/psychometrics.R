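#' Per-trial stimulus strength
#'
#' The overall stimulus strength of a trial is the average rating in favor
#' of the trial's target over all four words minus the average rating in
#' favor of the non-target (self ratings are the target dimension in the
#' self condition, other ratings in the other condition).  Raw strengths
#' are standardized per participant by dividing by their standard deviation
#' (n-1 denominator), so a strength of zero remains a genuinely neutral
#' stimulus -- the point at which an unbiased observer is correct with
#' probability one half, which is what the choice-function intercept is
#' meant to index.  Set `center = TRUE` for conventional mean-centered
#' z-scores; note that the staircase keeps the average stimulus
#' informative, so with centering the intercept reflects accuracy at the
#' average stimulus (near the staircase equilibrium), not response bias at
#' a neutral one.
#'
#' @param log a `trial_log`, possibly spanning several participants.
#' @param center subtract the per-participant mean before scaling
#'   (default `FALSE`).
#' @return `log` with columns `raw_strength` and `strength` (standardized
#'   per participant) appended.
#' @export
stimulus_strength <- function(log, center = FALSE) {
  wpt <- words_per_trial(log)
  selfs <- as.matrix(log[paste0("self_", seq_len(wpt))])
  others <- as.matrix(log[paste0("other_", seq_len(wpt))])
  target_mean <- ifelse(log$condition == "self",
                        rowMeans(selfs), rowMeans(others))
  nontarget_mean <- ifelse(log$condition == "self",
                           rowMeans(others), rowMeans(selfs))
  log$raw_strength <- target_mean - nontarget_mean
  log$strength <- NA_real_
  for (pid in unique(log$participant_id)) {
    rows <- log$participant_id == pid
    x <- log$raw_strength[rows]
    if (sum(rows) < 2L || stats::sd(x) == 0) {
      stop("cannot z-score stimulus strength for participant '", pid,
           "': fewer than 2 trials or zero variance", call. = FALSE)
    }
    log$strength[rows] <- if (center) (x - mean(x)) / stats::sd(x) else
      x / stats::sd(x)
  }
  log
}

#' Fit a logistic choice function
#'
#' Maximum-likelihood logistic regression of correctness on stimulus
#' strength with an intercept (the common logit regression model).  The
#' intercept indexes bias at zero strength -- `plogis(intercept)` is the
#' predicted probability correct for a neutral stimulus -- and the slope
#' indexes sensitivity.  Complete separation is detected and flagged
#' (direction reported) instead of silently returning huge coefficients.
#'
#' @param strengths numeric stimulus strengths.
#' @param corrects logical (or 0/1) correctness per trial.
#' @param min_trials minimum trials required (default 10).
#' @return A one-row data frame with `intercept`, `slope`, `n_trials`,
#'   `converged` and `note`.
#' @export
fit_choice_function <- function(strengths, corrects, min_trials = 10) {
  corrects <- as.logical(corrects)
  keep <- is.finite(strengths) & !is.na(corrects)
  strengths <- strengths[keep]; corrects <- corrects[keep]
  n <- length(strengths)
  flagged <- function(note) {
    data.frame(intercept = NA_real_, slope = NA_real_, n_trials = n,
               converged = FALSE, note = note, stringsAsFactors = FALSE)
  }
  if (n < min_trials) return(flagged("too few trials"))
  if (all(corrects) || all(!corrects)) return(flagged("single outcome class"))
  # complete separation: some threshold splits the classes perfectly
  lo <- max(strengths[!corrects]); hi <- min(strengths[corrects])
  if (lo < hi) return(flagged("complete separation (correct above)"))
  if (max(strengths[corrects]) < min(strengths[!corrects])) {
    return(flagged("complete separation (correct below)"))
  }
  fit <- suppressWarnings(
    stats::glm(corrects ~ strengths, family = stats::binomial()))
  cf <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(cf)) || any(abs(cf) > 50)) {
    return(flagged("glm did not converge"))
  }
  data.frame(intercept = unname(cf[1]), slope = unname(cf[2]), n_trials = n,
             converged = TRUE, note = "", stringsAsFactors = FALSE)
}

#' Per-participant median split of confidence
#'
#' Trials strictly above the participant's median confidence are labelled
#' `"high"`, those at or below it `"low"` (ties go to low: deterministic
#' and conservative for high-confidence contrasts).  All-equal confidence
#' yields all-low with a warning.
#'
#' @param confidences numeric confidences of one participant.
#' @return Character vector of `"low"`/`"high"` labels.
#' @export
median_split <- function(confidences) {
  if (length(confidences) < 2L) stop("median split needs >= 2 trials",
                                     call. = FALSE)
  m <- stats::median(confidences)
  if (all(confidences == m)) {
    warning("all confidences equal; every trial labelled 'low'")
    return(rep("low", length(confidences)))
  }
  ifelse(confidences > m, "high", "low")
}

#' Fit choice functions per participant, condition and confidence level
#'
#' Computes stimulus strength, labels each trial low/high confidence by
#' the participant's median split, and fits [fit_choice_function()] in
#' every participant x condition x confidence-level cell (levels `"all"`,
#' `"low"`, `"high"`; conditions `"self"`, `"other"` plus pooled
#' `"all"`).
#'
#' @param log a `trial_log`.
#' @param min_trials per-cell minimum trials.
#' @return Data frame of fits with columns `participant_id`, `condition`,
#'   `confidence_level`, `intercept`, `slope`, `n_trials`, `converged`,
#'   `note`.
#' @export
fit_choice_functions <- function(log, min_trials = 10) {
  log <- stimulus_strength(log)
  log$conf_level <- NA_character_
  for (pid in unique(log$participant_id)) {
    rows <- log$participant_id == pid
    log$conf_level[rows] <- median_split(log$confidence[rows])
  }
  cells <- expand.grid(participant_id = unique(log$participant_id),
                       condition = c("self", "other", "all"),
                       confidence_level = c("all", "low", "high"),
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- log$participant_id == cells$participant_id[i] &
      (cells$condition[i] == "all" | log$condition == cells$condition[i]) &
      (cells$confidence_level[i] == "all" |
         log$conf_level == cells$confidence_level[i])
    fit <- fit_choice_function(log$strength[sel], log$correct[sel],
                               min_trials)
    out[[i]] <- cbind(cells[i, , drop = FALSE], fit)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate choice-function fits across participants
#'
#' Averages intercepts and slopes per condition x confidence-level cell
#' (converged fits only, non-converged counted) and runs the paired
#' comparisons of interest: high vs. low confidence slopes and intercepts
#' within condition, and self vs. other within confidence level.
#'
#' @param fits output of [fit_choice_functions()].
#' @return List with `cells` (per-cell mean/SD/n), `tests` (paired t-test
#'   table) and `n_nonconverged`.
#' @export
aggregate_fits <- function(fits) {
  ok <- fits[fits$converged, , drop = FALSE]
  agg <- function(df) {
    data.frame(mean_intercept = mean(df$intercept),
               sd_intercept = stats::sd(df$intercept),
               mean_slope = mean(df$slope),
               sd_slope = stats::sd(df$slope), n = nrow(df))
  }
  keys <- unique(ok[c("condition", "confidence_level")])
  cells <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- ok[ok$condition == keys$condition[i] &
                ok$confidence_level == keys$confidence_level[i], ]
    cbind(keys[i, , drop = FALSE], agg(sub))
  }))
  rownames(cells) <- NULL

  paired_cells <- function(cond_a, lev_a, cond_b, lev_b, what) {
    a <- ok[ok$condition == cond_a & ok$confidence_level == lev_a, ]
    b <- ok[ok$condition == cond_b & ok$confidence_level == lev_b, ]
    common <- intersect(a$participant_id, b$participant_id)
    if (length(common) < 2L) return(NULL)
    if (!setequal(a$participant_id, b$participant_id)) {
      stop("unbalanced participant sets across compared cells",
           call. = FALSE)
    }
    x <- a[[what]][match(common, a$participant_id)]
    y <- b[[what]][match(common, b$participant_id)]
    tt <- t_test_report(x, y, paired = TRUE)
    data.frame(comparison = paste0(what, ": ", cond_a, "/", lev_a, " vs ",
                                   cond_b, "/", lev_b),
               t = tt$statistic, df = tt$df, p = tt$p_value,
               mean_diff = mean(x - y), stringsAsFactors = FALSE)
  }
  tests <- list()
  for (cond in c("self", "other")) {
    for (what in c("slope", "intercept")) {
      tests[[length(tests) + 1L]] <-
        paired_cells(cond, "high", cond, "low", what)
    }
  }
  for (lev in c("low", "high")) {
    for (what in c("slope", "intercept")) {
      tests[[length(tests) + 1L]] <-
        paired_cells("self", lev, "other", lev, what)
    }
  }
  tests <- do.call(rbind, tests)
  list(cells = cells, tests = tests,
       n_nonconverged = sum(!fits$converged))
}
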