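#' Sampler configuration
#'
#' Parameters of the per-trial adjective sampler: an isotropic (zero
#' covariance) two-dimensional Gaussian in rating space, centered at the
#' staircase position on the major diagonal, with per-word probabilities
#' corrected by the density of words on the evidence scale.
#'
#' @param sigma per-condition standard deviation of the selection Gaussian
#'   in rating units; either a single value, a named vector
#'   `c(self = , other = )`, or `NULL` to derive it from `sigma_scale`.
#' @param sigma_scale when `sigma` is `NULL`, the initial sigma is
#'   `sigma_scale` times the distance (in evidence units) between the two
#'   staircase start positions.
#' @param kde_bandwidth bandwidth of the evidence-scale kernel density
#'   estimate, or `"auto"` for Silverman's rule.
#' @param words_per_trial words drawn per trial (default 4).
#' @param calibrate logical; equalize the sampled-rating variance across
#'   conditions before a session (see [calibrate_sigma()]).
#' @param calibration_tolerance relative variance difference tolerated by
#'   the calibration (default 0.1).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(sigma = NULL, sigma_scale = 0.25,
                           kde_bandwidth = "auto", words_per_trial = 4,
                           calibrate = TRUE, calibration_tolerance = 0.1) {
  if (!is.null(sigma) && any(sigma <= 0)) {
    stop("sigma must be positive", call. = FALSE)
  }
  stopifnot(sigma_scale > 0, words_per_trial >= 1)
  structure(list(sigma = sigma, sigma_scale = sigma_scale,
                 kde_bandwidth = kde_bandwidth,
                 words_per_trial = as.integer(words_per_trial),
                 calibrate = calibrate,
                 calibration_tolerance = calibration_tolerance),
            class = "sampler_config")
}

#' Kernel density of the lexicon on the evidence scale
#'
#' Gaussian-kernel density estimate of the word evidence values, evaluated
#' at each word's own evidence.  Used to down-weight overpopulated evidence
#' regions during sampling.  With all-equal evidence values a uniform
#' density is returned with a warning.
#'
#' @param ratings a [as_standard_ratings()] object.
#' @param bandwidth numeric bandwidth; `"auto"` for Silverman's rule
#'   ([stats::bw.nrd0()], adequate for roughly unimodal evidence
#'   distributions); or `"sj"` for Sheather-Jones ([stats::bw.SJ()],
#'   recommended for strongly clustered evidence, where Silverman
#'   over-smooths and under-corrects the dense regions).
#' @return Strictly positive numeric vector, one density per word.
#' @export
estimate_density <- function(ratings, bandwidth = "auto") {
  ratings <- as_standard_ratings(ratings)
  e <- ratings$evidence
  if (length(unique(e)) < 2L) {
    warning("degenerate evidence values; using uniform density")
    return(rep(1 / 200, length(e)))
  }
  bw <- if (identical(bandwidth, "auto")) {
    stats::bw.nrd0(e)
  } else if (identical(bandwidth, "sj")) {
    tryCatch(stats::bw.SJ(e), error = function(err) stats::bw.nrd0(e))
  } else {
    bandwidth
  }
  stopifnot(is.finite(bw), bw > 0)
  # KDE evaluated at the data points themselves
  dens <- vapply(e, function(x) mean(stats::dnorm(x - e, sd = bw)),
                 numeric(1))
  pmax(dens, .Machine$double.xmin)
}

#' Per-word selection probabilities
#'
#' Each word's probability of selection is proportional to its value under
#' an isotropic bivariate Gaussian centered at the staircase's diagonal
#' point, divided by the word density on the evidence scale (so that
#' overpopulated evidence values are not overrepresented), normalized to
#' sum to one.  If the center is so far from every word that all densities
#' underflow, the probability mass falls back uniformly onto the nearest
#' word(s), with a warning.
#'
#' @param ratings a [as_standard_ratings()] object.
#' @param center a one-row [diagonal_point()] data frame (columns
#'   `self_coord`, `other_coord`).
#' @param sigma standard deviation of the selection Gaussian (rating units).
#' @param density per-word density from [estimate_density()]; `NULL`
#'   disables the density correction.
#' @return Numeric probability vector summing to 1.
#' @export
selection_probabilities <- function(ratings, center, sigma, density = NULL) {
  ratings <- as_standard_ratings(ratings)
  stopifnot(sigma > 0)
  if (!is.null(density)) {
    stopifnot(length(density) == nrow(ratings), all(density > 0))
  }
  # log-space for numerical robustness far from the word cloud
  lg <- stats::dnorm(ratings$self_rating, center$self_coord, sigma,
                     log = TRUE) +
    stats::dnorm(ratings$other_rating, center$other_coord, sigma, log = TRUE)
  if (!is.null(density)) lg <- lg - log(density)
  underflow <- max(lg) < log(.Machine$double.xmin)
  lg <- lg - max(lg)
  w <- exp(lg)
  if (underflow || !all(is.finite(w)) || sum(w) <= 0) {
    warning("selection probabilities underflow; falling back to nearest word")
    d2 <- (ratings$self_rating - center$self_coord)^2 +
      (ratings$other_rating - center$other_coord)^2
    w <- as.numeric(d2 == min(d2))
  }
  w / sum(w)
}

#' Draw the words of one trial
#'
#' Sequential sampling without replacement (probabilities renormalized
#' after each draw) of `n_words` distinct words, followed by an in-place
#' shuffle so that every word-position pairing is equally likely.  All
#' randomness comes from the R RNG stream, so trials are reproducible given
#' a seed.
#'
#' @inheritParams selection_probabilities
#' @param n_words number of words per trial (default 4).
#' @param probs optional precomputed [selection_probabilities()] vector
#'   (avoids recomputation inside session loops).
#' @return Integer vector of row indices into `ratings`, in presentation
#'   order.
#' @export
sample_trial_words <- function(ratings, center, sigma, density = NULL,
                               n_words = 4, probs = NULL) {
  if (nrow(ratings) < n_words) {
    stop("lexicon too small: ", nrow(ratings), " words for a ", n_words,
         "-word trial", call. = FALSE)
  }
  p <- if (is.null(probs)) {
    selection_probabilities(ratings, center, sigma, density)
  } else {
    probs
  }
  avail <- seq_along(p)
  picked <- integer(n_words)
  for (i in seq_len(n_words)) {
    if (length(avail) == 1L) {
      j <- avail
    } else if (sum(p[avail]) <= 0) {
      j <- avail[sample.int(length(avail), 1L)]
    } else {
      j <- avail[sample.int(length(avail), 1L, prob = p[avail])]
    }
    picked[i] <- j
    avail <- avail[avail != j]
  }
  picked[sample.int(n_words, n_words)]
}

#' Calibrate per-condition sampler sigmas
#'
#' Because words occupy the rating space non-uniformly, the same Gaussian
#' sigma can yield different spreads of sampled ratings in the two
#' conditions.  This routine simulates draws at each condition's staircase
#' start position and rescales the per-condition sigmas until the empirical
#' variances of the sampled words' ratings agree to within `tolerance`
#' (relative).  A non-finite tolerance returns the initial sigmas
#' unchanged; non-convergence returns the best iterate with a warning.
#'
#' @param ratings a [as_standard_ratings()] object.
#' @param sigma0 named numeric `c(self = , other = )` of initial sigmas.
#' @param starts named numeric `c(self = , other = )` staircase start
#'   positions on the evidence scale.
#' @param density per-word density from [estimate_density()].
#' @param n_sim simulated trials per condition per iteration (default 300).
#' @param words_per_trial words per simulated trial.
#' @param tolerance relative variance difference to accept (default 0.1).
#' @param max_iter maximum iterations (default 25).
#' @return List with `sigma` (named vector), `achieved_ratio` (variance
#'   ratio self/other), `iterations` and `converged`.
#' @export
calibrate_sigma <- function(ratings, sigma0, starts, density = NULL,
                            n_sim = 300, words_per_trial = 4,
                            tolerance = 0.1, max_iter = 25) {
  stopifnot(all(c("self", "other") %in% names(sigma0)),
            all(c("self", "other") %in% names(starts)))
  sigma <- sigma0
  if (!is.finite(tolerance)) {
    return(list(sigma = sigma, achieved_ratio = NA_real_, iterations = 0L,
                converged = TRUE))
  }
  measure <- function(cond) {
    center <- diagonal_point(starts[[cond]])
    vals <- replicate(n_sim, {
      idx <- sample_trial_words(ratings, center, sigma[[cond]], density,
                                words_per_trial)
      c(ratings$self_rating[idx], ratings$other_rating[idx])
    })
    stats::var(as.vector(vals))
  }
  ratio <- NA_real_
  prev_sigma <- prev_v <- NULL
  for (it in seq_len(max_iter)) {
    v <- c(self = measure("self"), other = measure("other"))
    ratio <- v[["self"]] / v[["other"]]
    rel_diff <- abs(v[["self"]] - v[["other"]]) / max(v)
    if (rel_diff <= tolerance) {
      return(list(sigma = sigma, achieved_ratio = ratio, iterations = it,
                  converged = TRUE))
    }
    # secant step on log variance vs log sigma per condition; the local
    # response slope is ~2 in the Gaussian-dominated regime but flattens
    # once the local word supply saturates the sampled spread
    target <- exp(mean(log(v)))
    slope <- c(self = 2, other = 2)
    if (!is.null(prev_sigma)) {
      for (cond in c("self", "other")) {
        ds <- log(sigma[[cond]]) - log(prev_sigma[[cond]])
        dv <- log(v[[cond]]) - log(prev_v[[cond]])
        if (abs(ds) > 1e-8 && is.finite(dv / ds)) {
          slope[[cond]] <- min(max(dv / ds, 0.15), 4)
        }
      }
    }
    prev_sigma <- sigma; prev_v <- v
    sigma <- sigma * exp((log(target) - log(v)) / slope)
  }
  warning("calibrate_sigma did not converge in ", max_iter,
          " iterations (variance ratio ", signif(ratio, 3), ")")
  list(sigma = sigma, achieved_ratio = ratio, iterations = max_iter,
       converged = FALSE)
}
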