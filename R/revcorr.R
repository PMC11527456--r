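#' Stimulus fluctuations of a trial log
#'
#' A word's fluctuation is its rating minus the trial's expected rating on
#' that dimension -- the mean rating of a word drawn by the staircase
#' selection algorithm on that trial, logged with the trial -- so
#' fluctuations capture the random part of stimulus sampling that reverse
#' correlation relates back to responses, and are mean-zero by
#' construction of the selection expectation.
#'
#' @param log a `trial_log` with `expected_self`/`expected_other` columns.
#' @return A long data frame: one row per trial x word position, with
#'   `participant_id`, `trial`, `position`, `choice`, `confidence`,
#'   `self_fluct`, `other_fluct`.
#' @export
fluctuations <- function(log) {
  wpt <- words_per_trial(log)
  if (is.null(log$expected_self) || is.null(log$expected_other) ||
      anyNA(log$expected_self) || anyNA(log$expected_other)) {
    stop("trial log lacks expected ratings (staircase centers)",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(wpt), function(pos) {
    data.frame(participant_id = log$participant_id, trial = log$trial,
               position = pos, choice = log$choice,
               confidence = log$confidence,
               self_fluct = log[[paste0("self_", pos)]] - log$expected_self,
               other_fluct = log[[paste0("other_", pos)]] -
                 log$expected_other,
               stringsAsFactors = FALSE)
  }))
  out[order(out$participant_id, out$trial, out$position), ]
}

# shared core: normalized, choice-relabelled per-cell means
weights_from_fluct <- function(fl, normalize, sd_scope) {
  res <- list()
  for (pid in unique(fl$participant_id)) {
    sub <- fl[fl$participant_id == pid, ]
    if (normalize) {
      norm_dim <- function(x, pos) {
        if (sd_scope == "pooled") {
          s <- stats::sd(x)
          if (s == 0) stop("zero fluctuation SD for participant '", pid,
                           "'", call. = FALSE)
          x / s
        } else {
          out <- x
          for (p in unique(pos)) {
            s <- stats::sd(x[pos == p])
            if (s == 0) stop("zero fluctuation SD for participant '", pid,
                             "' at position ", p, call. = FALSE)
            out[pos == p] <- x[pos == p] / s
          }
          out
        }
      }
      sub$self_fluct <- norm_dim(sub$self_fluct, sub$position)
      sub$other_fluct <- norm_dim(sub$other_fluct, sub$position)
    }
    # relabel by the trial's response: the chosen dimension's fluctuation
    chosen <- ifelse(sub$choice == "self", sub$self_fluct, sub$other_fluct)
    nonchosen <- ifelse(sub$choice == "self", sub$other_fluct,
                        sub$self_fluct)
    for (cong in c("chosen", "nonchosen")) {
      v <- if (cong == "chosen") chosen else nonchosen
      for (p in sort(unique(sub$position))) {
        sel <- sub$position == p
        res[[length(res) + 1L]] <- data.frame(
          participant_id = pid, congruence = cong, position = p,
          value = mean(v[sel]), n = sum(sel), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Decision weights via reverse correlation
#'
#' Raw fluctuations are divided by their standard deviation over all
#' trials (per participant and rating dimension, pooled over word
#' positions by default), relabelled as chosen / non-chosen by the trial's
#' response, and averaged per congruence x word-position cell.  Positive
#' chosen and negative non-chosen weights of equal magnitude are the
#' signature of a symmetric, balance-of-evidence choice rule.
#'
#' @param log a `trial_log` (or a precomputed [fluctuations()] frame).
#' @param normalize divide by the fluctuation SD (default `TRUE`).
#' @param min_trials minimum trials per participant (default 20).
#' @param sd_scope `"pooled"` (SD over all trials and positions, per
#'   dimension -- the default convention) or `"per_position"`.
#' @return Long data frame of class `weight_matrix`: `participant_id`,
#'   `kind`, `congruence` (`"chosen"`/`"nonchosen"`), `position`, `value`,
#'   `n`.
#' @export
decision_weights <- function(log, normalize = TRUE, min_trials = 20,
                             sd_scope = c("pooled", "per_position")) {
  sd_scope <- match.arg(sd_scope)
  fl <- if (all(c("self_fluct", "other_fluct") %in% names(log))) log else
    fluctuations(log)
  counts <- table(fl$participant_id) / max(fl$position)
  low <- names(counts)[counts < min_trials]
  if (length(low) > 0L) {
    stop("fewer than ", min_trials, " trials for participant(s): ",
         paste(low, collapse = ", "), call. = FALSE)
  }
  out <- weights_from_fluct(fl, normalize, sd_scope)
  out <- cbind(out[1], kind = "decision", out[-1])
  class(out) <- c("weight_matrix", "data.frame")
  out
}

#' Confidence weights (high minus low confidence decision weights)
#'
#' Decision weights are computed separately on high- and low-confidence
#' trials (per-participant median split by default) and subtracted
#' (high - low), yielding difference weights that quantify how stimulus
#' fluctuations drive the confidence report.  Near-zero non-chosen
#' confidence weights with positive chosen weights are the positive
#' evidence bias.
#'
#' @param log a `trial_log`.
#' @param split optional per-trial `"low"`/`"high"` labels aligned with
#'   `log`; `NULL` computes a per-participant [median_split()].
#' @param normalize,min_trials,sd_scope passed to [decision_weights()];
#'   the normalizing SD is taken over all of a participant's trials before
#'   splitting.
#' @return A `weight_matrix` data frame with `kind = "confidence"`.
#' @export
confidence_weights <- function(log, split = NULL, normalize = TRUE,
                               min_trials = 20,
                               sd_scope = c("pooled", "per_position")) {
  sd_scope <- match.arg(sd_scope)
  if (is.null(split)) {
    split <- rep(NA_character_, nrow(log))
    for (pid in unique(log$participant_id)) {
      rows <- log$participant_id == pid
      split[rows] <- median_split(log$confidence[rows])
    }
  }
  stopifnot(length(split) == nrow(log))
  for (lev in c("low", "high")) {
    if (!any(split == lev)) stop("confidence level '", lev, "' is empty",
                                 call. = FALSE)
  }
  fl <- fluctuations(log)
  # normalize on all trials, then split, so both levels share the scale
  fl_norm <- weights_normalize_only(fl, sd_scope)
  lev_of <- split[match(paste(fl$participant_id, fl$trial),
                        paste(log$participant_id, log$trial))]
  w_high <- weights_from_fluct(fl_norm[lev_of == "high", ],
                               normalize = FALSE, sd_scope)
  w_low <- weights_from_fluct(fl_norm[lev_of == "low", ],
                              normalize = FALSE, sd_scope)
  key <- function(w) paste(w$participant_id, w$congruence, w$position)
  m <- match(key(w_high), key(w_low))
  out <- w_high
  out$value <- w_high$value - w_low$value[m]
  out$n <- w_high$n + w_low$n[m]
  out <- cbind(out[1], kind = "confidence", out[-1])
  class(out) <- c("weight_matrix", "data.frame")
  out
}

weights_normalize_only <- function(fl, sd_scope) {
  for (pid in unique(fl$participant_id)) {
    rows <- fl$participant_id == pid
    for (col in c("self_fluct", "other_fluct")) {
      if (sd_scope == "pooled") {
        s <- stats::sd(fl[[col]][rows])
        if (s == 0) stop("zero fluctuation SD for participant '", pid, "'",
                         call. = FALSE)
        fl[[col]][rows] <- fl[[col]][rows] / s
      } else {
        for (p in unique(fl$position[rows])) {
          sel <- rows & fl$position == p
          s <- stats::sd(fl[[col]][sel])
          if (s == 0) stop("zero fluctuation SD for participant '", pid,
                           "' at position ", p, call. = FALSE)
          fl[[col]][sel] <- fl[[col]][sel] / s
        }
      }
    }
  }
  fl
}

#' Reshape a weight matrix to wide 2 x 4 form
#'
#' @param weights a `weight_matrix` data frame for one participant.
#' @return A 2 x positions numeric matrix, rows `chosen` / `nonchosen`.
#' @export
weight_table <- function(weights) {
  stopifnot(length(unique(weights$participant_id)) == 1L)
  pos <- sort(unique(weights$position))
  m <- matrix(NA_real_, 2, length(pos),
              dimnames = list(c("chosen", "nonchosen"), pos))
  for (i in seq_len(nrow(weights))) {
    m[weights$congruence[i], as.character(weights$position[i])] <-
      weights$value[i]
  }
  m
}
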