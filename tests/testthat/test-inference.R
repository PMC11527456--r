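long_table <- function(values, subjects, a_levels, b_levels) {
  g <- expand.grid(subject = subjects, A = a_levels, B = b_levels,
                   stringsAsFactors = FALSE)
  g$value <- values
  g
}

aov_oracle <- function(data) {
  # independent route through stats::aov error strata
  data$subject <- factor(data$subject)
  data$A <- factor(data$A); data$B <- factor(data$B)
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = data)
  s <- summary(fit)
  get <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, ]
  }
  list(A = get("Error: subject:A", "A"),
       B = get("Error: subject:B", "B"),
       AB = get("Error: subject:A:B", "A:B"))
}

test_that("the repeated-measures ANOVA matches the aov error-strata oracle", {
  set.seed(90)
  # handmade 3 x 2 x 2 and a larger random 8 x 2 x 4 design
  small <- long_table(c(4, 6, 9, 5, 8, 12, 3, 5, 8, 7, 9, 14),
                      paste0("s", 1:3), c("a1", "a2"), c("b1", "b2"))
  big <- long_table(stats::rnorm(8 * 2 * 4), paste0("s", 1:8),
                    c("a1", "a2"), paste0("b", 1:4))
  for (data in list(small, big)) {
    res <- rm_anova_2way(data, value = "value", subject = "subject",
                         factorA = "A", factorB = "B")
    orc <- aov_oracle(data)
    eff <- res$effects
    expect_equal(eff$F[eff$effect == "A"], orc$A[["F value"]],
                 tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "B"], orc$B[["F value"]],
                 tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "A:B"], orc$AB[["F value"]],
                 tolerance = 1e-8)
    expect_equal(eff$p[eff$effect == "A"], orc$A[["Pr(>F)"]],
                 tolerance = 1e-8)
    # generalized eta squared recomputed from the total decomposition:
    # ges_A = SS_A / (SS_A + SS_subjects + all error SS)
    #       = SS_A / (SS_total - SS_B - SS_AB)
    y <- data$value
    ss_total <- sum((y - mean(y))^2)
    ss_a <- eff$SS[eff$effect == "A"]
    denom <- ss_total - eff$SS[eff$effect == "B"] -
      eff$SS[eff$effect == "A:B"]
    expect_equal(eff$ges[eff$effect == "A"], ss_a / denom,
                 tolerance = 1e-10)
  }
})

test_that("the sums of squares decompose exactly and ignore subject labels", {
  set.seed(91)
  data <- long_table(stats::rnorm(6 * 2 * 4), paste0("s", 1:6),
                     c("x", "y"), paste0("b", 1:4))
  res <- rm_anova_2way(data, subject = "subject", factorA = "A",
                       factorB = "B")
  eff <- res$effects
  parts <- sum(eff$SS) + sum(eff$error_SS) + res$SS_subjects
  expect_equal(parts, res$SS_total, tolerance = 1e-8 * res$SS_total)

  relabeled <- data
  relabeled$subject <- chartr("123456", "642531", relabeled$subject)
  res2 <- rm_anova_2way(relabeled, subject = "subject", factorA = "A",
                        factorB = "B")
  expect_equal(res2$effects$F, eff$F)
  expect_equal(res2$effects$ges, eff$ges)
})

test_that("degenerate designs are flagged, not crashed", {
  # every subject flat across cells: all effects zero
  flat <- long_table(rep(c(1, 5, 9), times = 4), paste0("s", 1:3),
                     c("a1", "a2"), c("b1", "b2"))
  res <- rm_anova_2way(flat, subject = "subject", factorA = "A",
                       factorB = "B")
  expect_equal(res$effects$F, c(0, 0, 0))
  expect_true(all(res$effects$exact_fit))

  # value = subject effect + A effect, no noise: A is an exact fit
  g <- expand.grid(subject = paste0("s", 1:4), A = c("a1", "a2"),
                   B = c("b1", "b2"), stringsAsFactors = FALSE)
  g$value <- as.numeric(factor(g$subject)) + ifelse(g$A == "a2", 3, 0)
  res2 <- rm_anova_2way(g, subject = "subject", factorA = "A",
                        factorB = "B")
  eff2 <- res2$effects
  expect_true(eff2$exact_fit[eff2$effect == "A"])
  expect_equal(eff2$F[eff2$effect == "A"], Inf)
  expect_equal(eff2$F[eff2$effect == "B"], 0)

  missing_cell <- flat[-1, ]
  expect_error(rm_anova_2way(missing_cell, subject = "subject",
                             factorA = "A", factorB = "B"), "balanced")
  expect_error(rm_anova_2way(flat[flat$subject != "s3", ],
                             subject = "subject", factorA = "A",
                             factorB = "B"), "3 subjects")
})

test_that("t tests match the closed form and guard degenerate input", {
  expect_equal(t_test_report(c(-1, 0, 1))$statistic, 0)
  expect_equal(t_test_report(c(2, 5, 9), c(2, 5, 9))$statistic, 0)
  x <- c(1.2, -0.7, 0.4, 2.1, 0.9)
  tt <- t_test_report(x)
  expect_equal(tt$statistic, mean(x) / (stats::sd(x) / sqrt(5)),
               tolerance = 1e-10)
  expect_equal(tt$df, 4)
  expect_error(t_test_report(c(3, 3, 3)), "zero variance")
})

test_that("the inversion test certifies mirror-symmetric weights", {
  mk_weights <- function(values_chosen, values_nonchosen, n_sub = 5) {
    do.call(rbind, lapply(seq_len(n_sub), function(s) {
      data.frame(participant_id = paste0("p", s), kind = "decision",
                 congruence = rep(c("chosen", "nonchosen"), each = 4),
                 position = rep(1:4, 2),
                 value = c(values_chosen[s, ], values_nonchosen[s, ]),
                 n = 100, stringsAsFactors = FALSE)
    }))
  }
  set.seed(92)
  ch <- matrix(0.2 + stats::rnorm(20, 0, 0.02), 5, 4)
  mirror <- mk_weights(ch, -ch)
  st <- symmetry_test(mirror)
  expect_equal(st$congruence_inverted$F, 0)
  expect_true(st$symmetric)
  expect_lt(st$congruence_raw$p, 0.001)

  asym <- mk_weights(ch, matrix(0, 5, 4) +
                       stats::rnorm(20, 0, 0.01))
  st2 <- symmetry_test(asym)
  expect_lt(st2$congruence_inverted$p, 0.05)  # effect survives inversion
  expect_false(st2$symmetric)

  expect_error(symmetry_test(mirror[mirror$participant_id %in%
                                      c("p1", "p2"), ]), "3 participants")
})

test_that("the congruence F test keeps its nominal false-positive rate", {
  # random-responder weights: pure noise in every cell
  set.seed(93)
  n_rep <- 1000
  rejected <- logical(n_rep)
  g <- expand.grid(participant_id = paste0("p", 1:20),
                   congruence = c("chosen", "nonchosen"), position = 1:4,
                   stringsAsFactors = FALSE)
  for (r in seq_len(n_rep)) {
    g$value <- stats::rnorm(nrow(g))
    res <- rm_anova_2way(g, subject = "participant_id",
                         factorA = "congruence", factorB = "position")
    rejected[r] <- res$effects$p[res$effects$effect == "congruence"] < 0.05
  }
  ci <- binom_ci(sum(rejected), n_rep)
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("the confidence-bias report combines the ANOVA with position tests", {
  set.seed(94)
  g <- expand.grid(participant_id = paste0("p", 1:15),
                   congruence = c("chosen", "nonchosen"), position = 1:4,
                   stringsAsFactors = FALSE)
  g$value <- ifelse(g$congruence == "chosen", 0.3, 0) +
    stats::rnorm(nrow(g), 0, 0.05)
  cb <- confidence_bias_test(g)
  expect_lt(cb$congruence$p, 0.001)
  expect_equal(nrow(cb$position_tests), 4)
  expect_s3_class(cb$anova, "rm_anova")
})
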