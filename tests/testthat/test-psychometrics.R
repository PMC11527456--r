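test_that("stimulus strength is the target-minus-nontarget mean, standardized", {
  selfs <- matrix(c(60, 60, 60, 60,
                    55, 55, 55, 55), 2, 4, byrow = TRUE)
  others <- matrix(c(40, 40, 40, 40,
                     70, 70, 70, 70), 2, 4, byrow = TRUE)
  log <- make_log(condition = c("self", "other"),
                  choice = c("self", "other"),
                  confidence = c(60, 40), selfs = selfs, others = others)
  out <- stimulus_strength(log)
  # self-condition target dimension is self ratings; other condition flips
  expect_equal(out$raw_strength, c(20, 15))

  log2 <- random_log(400, seed = 80)
  st <- stimulus_strength(log2)
  expect_equal(stats::sd(st$strength), 1, tolerance = 1e-9)
  # scale-only: zero raw strength stays zero, ordering preserved
  expect_equal(st$strength, st$raw_strength / stats::sd(st$raw_strength))
  zc <- stimulus_strength(log2, center = TRUE)
  expect_equal(mean(zc$strength), 0, tolerance = 1e-9)
  expect_equal(stats::sd(zc$strength), 1, tolerance = 1e-9)
})

test_that("logistic choice fits recover known parameters and flag degeneracy", {
  set.seed(81)
  n <- 5000
  x <- stats::rnorm(n)
  y <- stats::runif(n) < stats::plogis(0 + 2 * x)
  fit <- fit_choice_function(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$slope - 2), 0.15)
  expect_lt(abs(fit$intercept - 0), 0.15)

  coin <- stats::runif(n) < 0.5
  null_fit <- fit_choice_function(x, coin)
  expect_lt(abs(null_fit$slope), 0.1)

  sep <- fit_choice_function(c(-2, -1, -0.5, 0.5, 1, 2, 3, 4, 5, 6),
                             c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                               TRUE, TRUE, TRUE))
  expect_false(sep$converged)
  expect_match(sep$note, "separation")
  expect_match(sep$note, "above")

  few <- fit_choice_function(x[1:5], y[1:5])
  expect_false(few$converged)
})

test_that("the MLE matches a brute-force grid search on a small dataset", {
  x <- c(-1.5, -1.0, -0.5, -0.2, 0.3, 0.8, 1.2, 2.0)
  y <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  fit <- fit_choice_function(x, y, min_trials = 8)
  loglik <- function(a, b) {
    p <- stats::plogis(a + b * x)
    sum(log(ifelse(y, p, 1 - p)))
  }
  # coarse-to-fine grid, final resolution 0.001
  best <- c(0, 0)
  for (res in c(0.05, 0.001)) {
    as_ <- seq(best[1] - 50 * res, best[1] + 50 * res, by = res)
    bs_ <- seq(best[2] - 50 * res, best[2] + 50 * res, by = res)
    ll <- outer(as_, bs_, Vectorize(loglik))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(as_[ix[1]], bs_[ix[2]])
  }
  expect_lt(abs(loglik(fit$intercept, fit$slope) -
                  loglik(best[1], best[2])), 1e-6)
  expect_gte(loglik(fit$intercept, fit$slope), loglik(best[1], best[2]))
})

test_that("fits are equivariant under rescaling of the strengths", {
  set.seed(82)
  x <- stats::rnorm(400)
  y <- stats::runif(400) < stats::plogis(0.3 + 1.5 * x)
  f1 <- fit_choice_function(x, y)
  f2 <- fit_choice_function(2 * x, y)
  expect_equal(f2$slope, f1$slope / 2, tolerance = 1e-6)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-6)
})

test_that("the confidence median split sends ties to low", {
  expect_equal(median_split(c(10, 20, 30, 40)),
               c("low", "low", "high", "high"))
  expect_equal(median_split(c(10, 20, 20, 40)),
               c("low", "low", "low", "high"))
  expect_warning(lab <- median_split(c(5, 5, 5)), "equal")
  expect_equal(lab, rep("low", 3))
  expect_error(median_split(7), ">= 2")
})

test_that("per-cell fits aggregate with paired comparisons", {
  fits <- expand.grid(participant_id = paste0("p", 1:6),
                      condition = c("self", "other"),
                      confidence_level = c("low", "high"),
                      stringsAsFactors = FALSE)
  set.seed(83)
  fits$intercept <- 0.1
  fits$slope <- ifelse(fits$confidence_level == "high", 2, 1) +
    stats::rnorm(nrow(fits), 0, 0.1)
  fits$n_trials <- 50; fits$converged <- TRUE; fits$note <- ""
  agg <- aggregate_fits(fits)
  cells <- agg$cells
  expect_equal(cells$mean_slope[cells$confidence_level == "high"], c(2, 2),
               tolerance = 0.2)
  # identical intercepts in compared cells: t = 0 by convention
  int_rows <- grepl("intercept", agg$tests$comparison)
  expect_true(all(agg$tests$t[int_rows] == 0))
  slope_hl <- agg$tests[grepl("slope: self/high vs self/low",
                              agg$tests$comparison), ]
  expect_equal(slope_hl$mean_diff, 1, tolerance = 0.25)
  expect_lt(slope_hl$p, 0.05)
})
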