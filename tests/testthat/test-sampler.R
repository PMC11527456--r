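test_that("selection probabilities normalize, respect symmetry and relabeling", {
  lex <- tiny_lexicon(8)
  rat <- tiny_ratings(lex)
  center <- diagonal_point(0)

  one <- as_standard_ratings(rat[1, 1:3])
  expect_equal(selection_probabilities(one, center, 10, NULL), 1)

  # two words mirror-symmetric about the center, equal density
  two <- as_standard_ratings(data.frame(word = c("a", "b"),
                                        self_rating = c(60, 40),
                                        other_rating = c(40, 60)))
  p <- selection_probabilities(two, center, 10, c(1, 1))
  expect_equal(p, c(0.5, 0.5))

  dens <- estimate_density(rat)
  p <- selection_probabilities(rat, center, 8, dens)
  expect_equal(sum(p), 1)
  # relabeling invariance: permuting rows permutes probabilities
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  p2 <- selection_probabilities(as_standard_ratings(rat[perm, 1:3]),
                                center, 8, dens[perm])
  expect_equal(p2, p[perm])

  # far-away center underflows every word: nearest-word fallback
  far <- as_standard_ratings(data.frame(word = c("a", "b"),
                                        self_rating = c(0, 10),
                                        other_rating = c(100, 90)))
  expect_warning(
    pf <- selection_probabilities(far, diagonal_point(100), 0.5, NULL),
    "nearest")
  expect_equal(pf, c(0, 1))
})

test_that("evidence-scale KDE matches stats::density and handles degeneracy", {
  lex <- generate_fixture_lexicon(60, seed = 3)
  rat <- generate_standard_ratings(lex, observer_params(), seed = 4)
  dens <- estimate_density(rat)
  # independent route: stats::density on the same bandwidth, interpolated
  ref <- stats::density(rat$evidence, bw = stats::bw.nrd0(rat$evidence),
                        n = 2048)
  at_words <- stats::approx(ref$x, ref$y, xout = rat$evidence)$y
  expect_equal(dens, at_words, tolerance = 1e-3)
  expect_true(all(dens > 0))

  # two equal clusters give equal density at the two cluster centers
  sym <- as_standard_ratings(data.frame(
    word = paste0("w", 1:8),
    self_rating = c(75, 76, 74, 75, 25, 26, 24, 25),
    other_rating = c(25, 24, 26, 25, 75, 74, 76, 75)))
  d <- estimate_density(sym, bandwidth = 5)
  expect_equal(d[1], d[5])

  # uniform grid of evidence: near-constant density away from the edges
  n <- 81
  grid <- as_standard_ratings(data.frame(
    word = paste0("g", 1:n),
    self_rating = (100 + seq(-80, 80, length.out = n)) / 2,
    other_rating = (100 - seq(-80, 80, length.out = n)) / 2))
  dg <- estimate_density(grid, bandwidth = 4)
  inner <- dg[abs(grid$evidence) < 60]
  expect_true(all(abs(inner - 1 / 160) / (1 / 160) < 0.1))

  flat <- as_standard_ratings(data.frame(word = c("a", "b"),
                                         self_rating = c(50, 50),
                                         other_rating = c(50, 50)))
  expect_warning(df <- estimate_density(flat), "uniform")
  expect_true(all(df > 0))
})

test_that("trial sampling draws distinct words and shuffles positions uniformly", {
  four <- tiny_ratings(tiny_lexicon(4))
  dens <- rep(1 / 200, 4)
  center <- diagonal_point(0)

  set.seed(10)
  perms <- replicate(6000, paste(
    sample_trial_words(four, center, 10, dens, 4), collapse = ""))
  expect_equal(sort(unique(nchar(perms))), 4)  # all four words, always
  counts <- table(perms)
  expect_equal(length(counts), 24)  # every permutation occurs
  chi <- stats::chisq.test(as.numeric(counts))
  expect_gt(chi$p.value, 0.001)

  rat <- tiny_ratings()
  set.seed(2); a <- sample_trial_words(rat, center, 10, NULL, 4)
  set.seed(2); b <- sample_trial_words(rat, center, 10, NULL, 4)
  set.seed(3); c <- sample_trial_words(rat, center, 10, NULL, 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_equal(anyDuplicated(a), 0L)

  set.seed(4)
  for (i in 1:300) {
    expect_equal(anyDuplicated(sample_trial_words(rat, center, 15, NULL, 4)),
                 0L)
  }
  expect_error(sample_trial_words(four, center, 10, NULL, 5), "too small")
})

test_that("sigma calibration equalizes sampled-rating variance across conditions", {
  # words dense on the self-favoring side, sparse on the other side
  set.seed(20)
  lex <- generate_fixture_lexicon(80, seed = 20)
  e <- c(runif(60, 5, 45), runif(20, -60, -5))
  u <- rnorm(80, 100, 10)
  rat <- as_standard_ratings(data.frame(
    word = lex$word,
    self_rating = pmin(pmax((u + e) / 2, 0), 100),
    other_rating = pmin(pmax((u - e) / 2, 0), 100)), lex)
  starts <- c(self = init_staircase("self", rat)$position,
              other = init_staircase("other", rat)$position)
  sigma0 <- c(self = 6, other = 6)

  untouched <- calibrate_sigma(rat, sigma0, starts, tolerance = Inf)
  expect_equal(untouched$sigma, sigma0)
  expect_equal(untouched$iterations, 0L)

  set.seed(21)
  cal <- calibrate_sigma(rat, sigma0, starts, n_sim = 400, tolerance = 0.1)
  expect_true(cal$converged)
  # independent post-hoc check of the achieved variance ratio
  set.seed(22)
  measure <- function(cond) {
    vals <- replicate(800, {
      idx <- sample_trial_words(rat, diagonal_point(starts[[cond]]),
                                cal$sigma[[cond]], NULL, 4)
      c(rat$self_rating[idx], rat$other_rating[idx])
    })
    stats::var(as.vector(vals))
  }
  v <- c(measure("self"), measure("other"))
  expect_lt(abs(v[1] - v[2]) / max(v), 0.2)
})

test_that("within-trial self and other ratings of sampled words are uncorrelated", {
  lex <- generate_fixture_lexicon(104, seed = 30)
  par <- observer_params()
  rat <- generate_standard_ratings(lex, par, seed = 31)
  log <- run_session(lex, rat, par, session_config(n_trials = 2000, seed = 32))
  fs <- as.matrix(log[paste0("self_", 1:4)]) - log$expected_self
  fo <- as.matrix(log[paste0("other_", 1:4)]) - log$expected_other
  expect_lt(abs(stats::cor(as.vector(fs), as.vector(fo))), 0.05)
})
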