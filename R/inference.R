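#' Two-way repeated-measures ANOVA with generalized eta squared
#'
#' Classical within-subject decomposition of a complete, balanced
#' subject x A x B table: sums of squares for subjects, the two factors,
#' their interaction, and the three error strata (subject x A,
#' subject x B, subject x A x B).  Each effect is tested against its own
#' error stratum.  Effect sizes are generalized eta squared,
#' `SS_effect / (SS_effect + SS_subjects + all error SS)` -- the
#' Olejnik-Algina form for fully within-subject designs.  An effect whose
#' error stratum has zero sum of squares is flagged `exact_fit` (F is
#' `Inf` when the effect SS is positive, 0 when it is zero) rather than
#' erroring.
#'
#' @param data long data frame with one value per subject x A x B cell.
#' @param value,subject,factorA,factorB column names in `data`.
#' @return A list of class `rm_anova` with `effects` (one row per effect:
#'   `effect`, `SS`, `df`, `error_SS`, `error_df`, `F`, `p`, `ges`,
#'   `exact_fit`), `SS_subjects`, `SS_total` and the factor names.
#' @export
rm_anova_2way <- function(data, value = "value", subject = "subject",
                          factorA = "A", factorB = "B") {
  y <- as.numeric(data[[value]])
  s <- factor(data[[subject]]); A <- factor(data[[factorA]])
  B <- factor(data[[factorB]])
  ns <- nlevels(s); na <- nlevels(A); nb <- nlevels(B)
  if (ns < 3L) stop("need at least 3 subjects", call. = FALSE)
  tab <- table(s, A, B)
  if (any(tab != 1L)) {
    stop("design must be complete and balanced with one value per ",
         "subject x A x B cell", call. = FALSE)
  }
  gm <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, A, mean)
  m_b <- tapply(y, B, mean)
  m_sa <- tapply(y, list(s, A), mean); m_sb <- tapply(y, list(s, B), mean)
  m_ab <- tapply(y, list(A, B), mean)

  ss_total <- sum((y - gm)^2)
  ss_s <- na * nb * sum((m_s - gm)^2)
  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + gm)^2)
  ss_sa <- nb * sum((m_sa - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + gm)^2)
  ss_sb <- na * sum((m_sb - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + gm)^2)
  ss_sab <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb
  ss_sab <- max(ss_sab, 0)

  ges_denom_err <- ss_s + ss_sa + ss_sb + ss_sab
  one <- function(name, ss, df, err_ss, err_df) {
    exact <- err_ss <= 1e-12 * max(ss_total, 1)
    f <- if (!exact) (ss / df) / (err_ss / err_df) else
      if (ss > 0) Inf else 0
    p <- if (is.finite(f)) stats::pf(f, df, err_df, lower.tail = FALSE) else
      if (is.infinite(f)) 0 else 1
    data.frame(effect = name, SS = ss, df = df, error_SS = err_ss,
               error_df = err_df, F = f, p = p,
               ges = if (ss + ges_denom_err > 0) ss / (ss + ges_denom_err)
                     else 0,
               exact_fit = exact, stringsAsFactors = FALSE)
  }
  effects <- rbind(
    one(factorA, ss_a, na - 1, ss_sa, (ns - 1) * (na - 1)),
    one(factorB, ss_b, nb - 1, ss_sb, (ns - 1) * (nb - 1)),
    one(paste0(factorA, ":", factorB), ss_ab, (na - 1) * (nb - 1),
        ss_sab, (ns - 1) * (na - 1) * (nb - 1)))
  structure(list(effects = effects, SS_subjects = ss_s,
                 SS_total = ss_total, factorA = factorA, factorB = factorB),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (within-subject:", x$factorA, "x",
      x$factorB, ")\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-20s F(%d,%d) = %.3f, p = %.4g, ges = %.4f%s\n",
                eff$effect[i], eff$df[i], eff$error_df[i], eff$F[i],
                eff$p[i], eff$ges[i],
                if (eff$exact_fit[i]) " [exact fit]" else ""))
  }
  invisible(x)
}

#' t test with explicit zero-variance guard
#'
#' Thin wrapper around [stats::t.test()] (one-sample or paired) that turns
#' the degenerate zero-variance case into an informative error and returns
#' a flat result structure.
#'
#' @param x numeric sample.
#' @param y optional second sample for a paired test.
#' @param mu null value for the one-sample test (default 0).
#' @param paired logical; `TRUE` with `y` runs a paired test.
#' @return List with `statistic`, `df`, `p_value`, `mean`.
#' @export
t_test_report <- function(x, y = NULL, mu = 0, paired = !is.null(y)) {
  if (!is.null(y)) {
    stopifnot(paired, length(x) == length(y))
    d <- x - y
  } else {
    d <- x - mu
  }
  if (length(d) < 2L) stop("t test needs n >= 2", call. = FALSE)
  if (stats::sd(d) == 0) {
    # identical paired vectors (or x == mu): no deviation at all is t = 0;
    # a nonzero mean difference with zero spread has no finite statistic
    if (all(d == 0)) {
      return(list(statistic = 0, df = length(d) - 1, p_value = 1,
                  mean = if (is.null(y)) mu else 0))
    }
    stop("zero variance in t test input", call. = FALSE)
  }
  tt <- if (is.null(y)) stats::t.test(x, mu = mu) else
    stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean = mean(d) + if (is.null(y)) mu else 0)
}

#' Weight-inversion symmetry test
#'
#' Tests whether non-chosen weights mirror chosen weights: (1) a
#' congruence x position repeated-measures ANOVA on the raw weights must
#' show a congruence effect; (2) after multiplying the non-chosen row by
#' -1, rerunning the ANOVA should remove that effect.  Symmetry is
#' supported when the raw effect is present and the post-inversion
#' congruence effect size falls below the smallness threshold.
#'
#' @param weights a `weight_matrix` data frame (one kind) across
#'   participants.
#' @param smallness generalized-eta-squared threshold below which the
#'   post-inversion effect counts as absent (default 0.01).
#' @return List with `raw` and `inverted` `rm_anova` objects, the two
#'   congruence-effect rows (`congruence_raw`, `congruence_inverted`) and
#'   the logical `symmetric`.
#' @export
symmetry_test <- function(weights, smallness = 0.01) {
  if (length(unique(weights$participant_id)) < 3L) {
    stop("need at least 3 participants", call. = FALSE)
  }
  raw <- rm_anova_2way(weights, value = "value",
                       subject = "participant_id",
                       factorA = "congruence", factorB = "position")
  inv <- weights
  flip <- inv$congruence == "nonchosen"
  inv$value[flip] <- -inv$value[flip]
  inverted <- rm_anova_2way(inv, value = "value",
                            subject = "participant_id",
                            factorA = "congruence", factorB = "position")
  cr <- raw$effects[raw$effects$effect == "congruence", ]
  ci <- inverted$effects[inverted$effects$effect == "congruence", ]
  list(raw = raw, inverted = inverted, congruence_raw = cr,
       congruence_inverted = ci,
       symmetric = isTRUE(cr$p < 0.05 && ci$ges < smallness))
}

#' Positive-evidence-bias test on confidence weights
#'
#' Runs the congruence x position repeated-measures ANOVA on confidence
#' weights and one-sample t-tests of the non-chosen weights against zero
#' at each word position.  The positive evidence bias is the combination
#' of a congruence effect (chosen above non-chosen) with non-chosen
#' weights that do not differ from zero.
#'
#' @param weights a `weight_matrix` of confidence weights.
#' @param alpha significance level for the per-position tests (default
#'   0.05).
#' @return List with `anova` (`rm_anova`), `congruence` (its congruence
#'   row), `position_tests` (data frame: position, t, df, p, mean) and
#'   logical `bias_pattern`.
#' @export
confidence_bias_test <- function(weights, alpha = 0.05) {
  an <- rm_anova_2way(weights, value = "value",
                      subject = "participant_id",
                      factorA = "congruence", factorB = "position")
  cong <- an$effects[an$effects$effect == "congruence", ]
  nonch <- weights[weights$congruence == "nonchosen", ]
  pos_tests <- do.call(rbind, lapply(sort(unique(nonch$position)),
                                     function(p) {
    v <- nonch$value[nonch$position == p]
    tt <- t_test_report(v, mu = 0)
    data.frame(position = p, t = tt$statistic, df = tt$df, p = tt$p_value,
               mean = mean(v))
  }))
  chosen_mean <- mean(weights$value[weights$congruence == "chosen"])
  list(anova = an, congruence = cong, position_tests = pos_tests,
       bias_pattern = isTRUE(cong$p < 0.001 && all(pos_tests$p > alpha) &&
                               chosen_mean > mean(nonch$value)))
}
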