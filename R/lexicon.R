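#' Adjective lexicon
#'
#' A lexicon is a data frame with one row per trait adjective and columns
#' `word`, `n_letters`, `n_syllables`, `log10_freq` and `valence`.  Words
#' must be unique; letter and syllable counts are positive integers.
#' `valence` is a signed rating-scale value and `log10_freq` a log10 corpus
#' frequency, both used only for filtering and display-time prediction.
#'
#' @param df data frame carrying the five lexicon columns.
#' @return An object of class `lexicon` (a validated data frame).
#' @export
as_lexicon <- function(df) {
  required <- c("word", "n_letters", "n_syllables", "log10_freq", "valence")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("lexicon is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$word <- as.character(df$word)
  if (any(!nzchar(df$word)) || anyNA(df$word)) {
    stop("lexicon words must be non-empty", call. = FALSE)
  }
  dup <- unique(df$word[duplicated(df$word)])
  if (length(dup) > 0L) {
    stop("duplicated word(s) in lexicon: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("n_letters", "n_syllables", "log10_freq", "valence")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop("non-finite values in lexicon column '", col, "'", call. = FALSE)
    }
  }
  if (any(df$n_letters < 1) || any(df$n_syllables < 1)) {
    stop("n_letters and n_syllables must be >= 1", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("lexicon", "data.frame")
  df
}

#' Read or write a lexicon file
#'
#' Lexicon files are UTF-8 delimited text (tab-separated by default) with a
#' header row and columns `word`, `n_letters`, `n_syllables`, `log10_freq`,
#' `valence`.  Row order is preserved.
#'
#' @param path file path.
#' @param sep field delimiter, `"\t"` by default.
#' @return `read_lexicon()` returns a validated [as_lexicon()] object;
#'   `write_lexicon()` returns `path` invisibly.
#' @export
read_lexicon <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", fileEncoding = "UTF-8")
  as_lexicon(df)
}

#' @rdname read_lexicon
#' @param lex a [as_lexicon()] object.
#' @export
write_lexicon <- function(lex, path, sep = "\t") {
  lex <- as_lexicon(lex)
  utils::write.table(lex, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter a lexicon on valence, frequency and length
#'
#' Retains adjectives that are weakly valenced (absolute valence at most
#' `max_abs_valence`), common (log10 frequency strictly above
#' `min_log10_freq`), short (strictly fewer than `max_letters` letters) and
#' not on an explicit exclusion list.  Original order is preserved and the
#' operation is idempotent.
#'
#' @param lex a lexicon.
#' @param max_abs_valence retain `|valence| <= max_abs_valence` (default 1.6).
#' @param min_log10_freq retain `log10_freq > min_log10_freq` (default 0.5);
#'   the cut drops rare words.
#' @param max_letters retain `n_letters < max_letters` (default 14).
#' @param exclusion_list character vector of words to drop regardless.
#' @return The filtered lexicon; a warning (not an error) if empty.
#' @export
filter_lexicon <- function(lex, max_abs_valence = 1.6, min_log10_freq = 0.5,
                           max_letters = 14, exclusion_list = character()) {
  lex <- as_lexicon(lex)
  stopifnot(is.finite(max_abs_valence), is.finite(min_log10_freq),
            is.finite(max_letters))
  keep <- abs(lex$valence) <= max_abs_valence &
    lex$log10_freq > min_log10_freq &
    lex$n_letters < max_letters &
    !(lex$word %in% exclusion_list)
  out <- lex[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("filter_lexicon: no words retained")
  class(out) <- c("lexicon", "data.frame")
  out
}

#' Display-time model coefficients
#'
#' Coefficients of a linear model predicting lexical decision time (ms) from
#' number of letters, number of syllables and log10 word frequency together
#' with all their interactions (a full three-way factorial of the three
#' surface properties).
#'
#' @param intercept,b_letters,b_syllables,b_freq main-effect coefficients.
#' @param b_letters_syllables,b_letters_freq,b_syllables_freq two-way
#'   interaction coefficients.
#' @param b_letters_syllables_freq three-way interaction coefficient.
#' @return A named numeric vector of class `display_model_coeffs`.
#' @export
display_model_coeffs <- function(intercept, b_letters = 0, b_syllables = 0,
                                 b_freq = 0, b_letters_syllables = 0,
                                 b_letters_freq = 0, b_syllables_freq = 0,
                                 b_letters_syllables_freq = 0) {
  cf <- c(intercept = intercept, b_letters = b_letters,
          b_syllables = b_syllables, b_freq = b_freq,
          b_letters_syllables = b_letters_syllables,
          b_letters_freq = b_letters_freq,
          b_syllables_freq = b_syllables_freq,
          b_letters_syllables_freq = b_letters_syllables_freq)
  if (any(!is.finite(cf))) stop("display model coefficients must be finite",
                                call. = FALSE)
  class(cf) <- "display_model_coeffs"
  cf
}

#' Fit display-time model coefficients to a decision-time corpus
#'
#' Ordinary least squares fit of lexical decision time on the full
#' three-way factorial of letters, syllables and log10 frequency, as used to
#' derive per-word display times.
#'
#' @param corpus data frame with columns `n_letters`, `n_syllables`,
#'   `log10_freq` and `ldt_ms` (observed lexical decision time, ms).
#' @return A [display_model_coeffs()] object.
#' @export
fit_display_model <- function(corpus) {
  stopifnot(all(c("n_letters", "n_syllables", "log10_freq", "ldt_ms") %in%
                  names(corpus)))
  fit <- stats::lm(ldt_ms ~ n_letters * n_syllables * log10_freq,
                   data = corpus)
  cf <- stats::coef(fit)
  display_model_coeffs(
    intercept = cf[["(Intercept)"]],
    b_letters = cf[["n_letters"]],
    b_syllables = cf[["n_syllables"]],
    b_freq = cf[["log10_freq"]],
    b_letters_syllables = cf[["n_letters:n_syllables"]],
    b_letters_freq = cf[["n_letters:log10_freq"]],
    b_syllables_freq = cf[["n_syllables:log10_freq"]],
    b_letters_syllables_freq = cf[["n_letters:n_syllables:log10_freq"]]
  )
}

#' Predicted display duration of an adjective
#'
#' Evaluates the display-time model for each word and returns the predicted
#' lexical decision time minus `offset_ms`, floored at `floor_ms`.  The
#' floor exists because arbitrary coefficients can predict implausibly short
#' (even negative) durations; realistic stimulus sets sit well above it.
#'
#' @param adj a lexicon (or any data frame with `n_letters`, `n_syllables`,
#'   `log10_freq`).
#' @param coeffs a [display_model_coeffs()] object.
#' @param offset_ms subtracted from the predicted decision time (default 117).
#' @param floor_ms minimum returned duration in ms (default 200).
#' @return Numeric vector of display durations in milliseconds.
#' @export
display_duration <- function(adj, coeffs, offset_ms = 117, floor_ms = 200) {
  if (!inherits(coeffs, "display_model_coeffs")) {
    coeffs <- do.call(display_model_coeffs, as.list(coeffs))
  }
  L <- adj$n_letters; S <- adj$n_syllables; f <- adj$log10_freq
  pred <- coeffs[["intercept"]] + coeffs[["b_letters"]] * L +
    coeffs[["b_syllables"]] * S + coeffs[["b_freq"]] * f +
    coeffs[["b_letters_syllables"]] * L * S +
    coeffs[["b_letters_freq"]] * L * f +
    coeffs[["b_syllables_freq"]] * S * f +
    coeffs[["b_letters_syllables_freq"]] * L * S * f
  pmax(pred - offset_ms, floor_ms)
}

#' Generate a synthetic fixture lexicon
#'
#' Deterministic (given `seed`) generator of a synthetic adjective lexicon
#' standing in for a validated trait-word list.  Surface properties are
#' drawn from a mixture of word-type clusters (e.g. short/frequent vs.
#' long/rare) and always respect the default filter bounds: 4-13 letters,
#' 1-5 syllables, log10 frequency above 0.5, absolute valence at most 1.6.
#' Word labels are unique synthetic strings.
#'
#' @param n_words number of words (at least 8, the sampler minimum for two
#'   four-word conditions).
#' @param seed integer seed.
#' @param cluster_spec list of cluster descriptions, each a list with
#'   `weight`, `letters` (range), `syllables` (range) and `freq_mean`/
#'   `freq_sd`; `NULL` for the built-in two-cluster default.
#' @return A [as_lexicon()] object of `n_words` rows.
#' @export
generate_fixture_lexicon <- function(n_words, seed, cluster_spec = NULL) {
  if (n_words < 8) stop("n_words must be >= 8", call. = FALSE)
  if (is.null(cluster_spec)) {
    cluster_spec <- list(
      list(weight = 0.6, letters = c(4, 8), syllables = c(1, 3),
           freq_mean = 2.0, freq_sd = 0.5),
      list(weight = 0.4, letters = c(8, 13), syllables = c(3, 5),
           freq_mean = 1.0, freq_sd = 0.3)
    )
  }
  set.seed(seed)
  w <- vapply(cluster_spec, function(cl) cl$weight, numeric(1))
  k <- sample.int(length(cluster_spec), n_words, replace = TRUE, prob = w)
  n_letters <- n_syllables <- log10_freq <- numeric(n_words)
  for (i in seq_len(n_words)) {
    cl <- cluster_spec[[k[i]]]
    n_letters[i] <- sample(seq(cl$letters[1], cl$letters[2]), 1)
    n_syllables[i] <- sample(seq(cl$syllables[1], cl$syllables[2]), 1)
    log10_freq[i] <- stats::rnorm(1, cl$freq_mean, cl$freq_sd)
  }
  log10_freq <- pmin(pmax(log10_freq, 0.51), 4)
  n_syllables <- pmin(n_syllables, n_letters)  # never more syllables than letters
  valence <- pmin(pmax(stats::rnorm(n_words, 0, 0.8), -1.6), 1.6)
  word <- sprintf("adj%03d_%s", seq_len(n_words),
                  vapply(seq_len(n_words), function(i) {
                    paste(sample(letters, 4, replace = TRUE), collapse = "")
                  }, character(1)))
  as_lexicon(data.frame(word = word, n_letters = n_letters,
                        n_syllables = n_syllables, log10_freq = log10_freq,
                        valence = valence))
}
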