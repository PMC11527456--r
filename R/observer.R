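#' Simulated observer parameters
#'
#' A simulated participant has a rating generator (how the standard self
#' and other ratings of the lexicon arise), a balanced-evidence choice rule
#' with additive Gaussian decision noise, and one of two confidence rules:
#'
#' * `"balanced"`: confidence increases with the absolute balance of
#'   evidence |mean(self - other)| of the trial's words -- both stimulus
#'   dimensions inform confidence.
#' * `"positive_evidence"`: confidence increases with the mean rating on
#'   the *chosen* dimension only (relative to the trial's expected center
#'   coordinate), discounting the non-chosen dimension -- the
#'   decision-congruent, positive-evidence-biased rule.
#'
#' @param choice_noise_sd SD of the Gaussian noise added to the mean
#'   evidence before the choice (evidence units; default 15).
#' @param confidence_model `"balanced"` or `"positive_evidence"`.
#' @param confidence_gain slope of confidence on its evidence input
#'   (default 0.7).
#' @param confidence_offset confidence at zero input (default 38).
#' @param confidence_noise_sd SD of the confidence report noise (default
#'   13).  The confidence defaults are calibrated so a default balanced
#'   observer reports confidence with a mean near 49, an SD near 15 and a
#'   correct-minus-error gap near 6 on the 0-100 scale -- the resolution
#'   typical of human metacognition in uncertain trait judgments.
#' @param rating_correlation correlation between a word's self and other
#'   rating (default 0.3, a similar-but-different other).
#' @param rating_mean,rating_sd marginal mean and SD of generated ratings
#'   on the 0-100 scale (defaults 50 and 20).
#' @param rating_bias additive bias of self ratings (default 0; exposed for
#'   studying biased standards).
#' @param e_clusters optional evidence mixture for clustered rating
#'   generation: a list with `centers`, `sds`, `weights` (recycled) and
#'   optionally `u_sd` (SD of self+other around 100, default 20).
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(choice_noise_sd = 15,
                            confidence_model = c("balanced",
                                                 "positive_evidence"),
                            confidence_gain = 0.7, confidence_offset = 38,
                            confidence_noise_sd = 13,
                            rating_correlation = 0.3, rating_mean = 50,
                            rating_sd = 20, rating_bias = 0,
                            e_clusters = NULL) {
  confidence_model <- match.arg(confidence_model)
  stopifnot(choice_noise_sd >= 0, confidence_noise_sd >= 0,
            rating_correlation >= -1, rating_correlation <= 1,
            rating_sd > 0, confidence_offset >= 0, confidence_offset <= 100)
  structure(list(choice_noise_sd = choice_noise_sd,
                 confidence_model = confidence_model,
                 confidence_gain = confidence_gain,
                 confidence_offset = confidence_offset,
                 confidence_noise_sd = confidence_noise_sd,
                 rating_correlation = rating_correlation,
                 rating_mean = rating_mean, rating_sd = rating_sd,
                 rating_bias = rating_bias, e_clusters = e_clusters),
            class = "observer_params")
}

#' Generate synthetic standard ratings for a lexicon
#'
#' Draws per-word (self, other) rating pairs from a bivariate Gaussian with
#' the configured marginals and correlation (or, when `e_clusters` is set,
#' from an evidence-mixture construction yielding a deliberately non-uniform
#' evidence density), clamped to the 0-100 scale.  Both conditions must be
#' initializable -- at least one word with positive and one with negative
#' evidence; degenerate draws are regenerated up to `max_attempts` times.
#'
#' @param lexicon a [as_lexicon()] object.
#' @param params an [observer_params()] object.
#' @param seed optional integer seed (set before drawing).
#' @param max_attempts regeneration attempts on degenerate spread.
#' @param require_both_sides enforce evidence on both sides of zero
#'   (default `TRUE`; set `FALSE` to study degenerate limits such as a
#'   perfectly correlated rater, for whom all evidence collapses to 0).
#' @return A [as_standard_ratings()] object aligned with `lexicon`.
#' @export
generate_standard_ratings <- function(lexicon, params = observer_params(),
                                      seed = NULL, max_attempts = 10,
                                      require_both_sides = TRUE) {
  lexicon <- as_lexicon(lexicon)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(lexicon)
  draw <- function() {
    if (!is.null(params$e_clusters)) {
      cl <- params$e_clusters
      k <- length(cl$centers)
      wts <- rep_len(if (is.null(cl$weights)) 1 else cl$weights, k)
      u_sd <- if (is.null(cl$u_sd)) 20 else cl$u_sd
      comp <- sample.int(k, n, replace = TRUE, prob = wts)
      e <- stats::rnorm(n, cl$centers[comp], rep_len(cl$sds, k)[comp])
      u <- stats::rnorm(n, 100, u_sd)
      s <- (u + e) / 2 + params$rating_bias
      o <- (u - e) / 2
    } else {
      rho <- params$rating_correlation
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      s <- params$rating_mean + params$rating_sd * z1 + params$rating_bias
      o <- params$rating_mean + params$rating_sd * z2
    }
    data.frame(word = lexicon$word,
               self_rating = pmin(pmax(s, 0), 100),
               other_rating = pmin(pmax(o, 0), 100))
  }
  for (attempt in seq_len(max_attempts)) {
    df <- draw()
    e <- df$self_rating - df$other_rating
    if (!require_both_sides || (any(e > 0) && any(e < 0))) {
      return(as_standard_ratings(df, lexicon))
    }
    warning("degenerate rating draw (all evidence on one side); retrying")
  }
  stop("could not generate non-degenerate ratings in ", max_attempts,
       " attempts", call. = FALSE)
}

#' Balanced-evidence decision variable
#'
#' @param self_ratings,other_ratings ratings of the trial's words.
#' @return `mean(self_ratings - other_ratings)`, the noiseless balance of
#'   evidence.
#' @export
decision_variable <- function(self_ratings, other_ratings) {
  mean(self_ratings - other_ratings)
}

#' Simulated choice of a trial
#'
#' The observer compares the mean evidence of the presented words to zero
#' after adding Gaussian decision noise: `d = mean(self - other) + eps`,
#' choosing "self" if `d > 0`, "other" if `d < 0`, and tossing a fair coin
#' at exactly zero.  Both the information for and against each alternative
#' enter the decision -- the symmetric, balance-of-evidence rule.
#' [observer_decide()] also returns the noisy internal decision variable
#' `d`, which the balanced confidence rule reuses: choice and confidence
#' read the same internal evidence, as in standard models of
#' decision-congruent confidence.
#'
#' @param self_ratings,other_ratings ratings of the trial's words.
#' @param params an [observer_params()] object.
#' @return `observer_decide()` returns `list(choice, d)`;
#'   `observer_choose()` returns just `"self"` or `"other"`.
#' @export
observer_decide <- function(self_ratings, other_ratings, params) {
  d <- decision_variable(self_ratings, other_ratings)
  if (params$choice_noise_sd > 0) {
    d <- d + stats::rnorm(1, 0, params$choice_noise_sd)
  }
  choice <- if (d > 0) "self" else if (d < 0) "other" else
    sample(c("self", "other"), 1)
  list(choice = choice, d = d)
}

#' @rdname observer_decide
#' @export
observer_choose <- function(self_ratings, other_ratings, params) {
  observer_decide(self_ratings, other_ratings, params)$choice
}

#' Simulated confidence report
#'
#' Under the balanced model confidence is `offset + gain * |d| + noise`,
#' where `d` is the same noisy internal decision variable that produced
#' the choice (pass it via `d`; if omitted, the noiseless balance of
#' evidence is used).  Under the positive-evidence model it is
#' `offset + gain * (mean rating on the chosen dimension - the trial's
#' expected rating on that dimension) + noise`.  Reports are clamped to
#' the 0-100 scale.
#'
#' @param self_ratings,other_ratings ratings of the trial's words.
#' @param choice `"self"` or `"other"`, the choice already made.
#' @param expected_self,expected_other the trial's expected ratings (the
#'   mean rating of a word drawn by the selection algorithm on that
#'   trial).
#' @param params an [observer_params()] object.
#' @param d the internal decision variable from [observer_decide()], or
#'   `NULL`.
#' @return Confidence in \[0, 100\].
#' @export
observer_confidence <- function(self_ratings, other_ratings, choice,
                                expected_self, expected_other, params,
                                d = NULL) {
  input <- switch(params$confidence_model,
    balanced = abs(if (is.null(d))
      decision_variable(self_ratings, other_ratings) else d),
    positive_evidence = if (choice == "self") {
      mean(self_ratings) - expected_self
    } else {
      mean(other_ratings) - expected_other
    })
  conf <- params$confidence_offset + params$confidence_gain * input
  if (params$confidence_noise_sd > 0) {
    conf <- conf + stats::rnorm(1, 0, params$confidence_noise_sd)
  }
  min(max(conf, 0), 100)
}
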