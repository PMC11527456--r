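#' Evidence carried by a pair of standard ratings
#'
#' The evidence of a word is its self rating minus its other rating, both on
#' the 0-100 visual-analog scale; positive evidence favors the "self"
#' response.  The attainable range is \[-100, 100\].
#'
#' @param self_rating,other_rating numeric ratings in \[0, 100\].
#' @return `self_rating - other_rating`, vectorized.
#' @export
evidence <- function(self_rating, other_rating) {
  if (any(self_rating < 0 | self_rating > 100) ||
      any(other_rating < 0 | other_rating > 100)) {
    stop("ratings must lie in [0, 100]", call. = FALSE)
  }
  self_rating - other_rating
}

#' Point on the major diagonal of the rating space
#'
#' The major diagonal of the (self, other) rating square traverses all
#' evidence values; a staircase position `e` maps to the unique point with
#' `self + other = 100` and `self - other = e`.
#'
#' @param position evidence value(s) in \[-100, 100\].
#' @return Data frame with columns `position`, `self_coord`, `other_coord`.
#' @export
diagonal_point <- function(position) {
  if (any(position < -100 | position > 100)) {
    stop("diagonal position must lie in [-100, 100]", call. = FALSE)
  }
  data.frame(position = position,
             self_coord = (100 + position) / 2,
             other_coord = (100 - position) / 2)
}

#' Standard ratings of a lexicon
#'
#' Per-word self and other ratings on the 0-100 scale, with the derived
#' evidence column `evidence = self_rating - other_rating`.  The word set
#' must match the parent lexicon exactly (same words, same order).
#'
#' @param df data frame with columns `word`, `self_rating`, `other_rating`.
#' @param lexicon the parent [as_lexicon()] object, or `NULL` to skip the
#'   word-set check.
#' @return An object of class `standard_ratings` (a data frame with an
#'   `evidence` column added).
#' @export
as_standard_ratings <- function(df, lexicon = NULL) {
  required <- c("word", "self_rating", "other_rating")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("ratings are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)
  df$word <- as.character(df$word)
  if (!is.null(lexicon)) {
    lexicon <- as_lexicon(lexicon)
    absent <- setdiff(lexicon$word, df$word)
    extra <- setdiff(df$word, lexicon$word)
    if (length(absent) > 0L || length(extra) > 0L) {
      stop("ratings do not match the lexicon word set",
           if (length(absent)) paste0("; missing: ",
                                      paste(absent, collapse = ", ")),
           if (length(extra)) paste0("; unknown: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
    df <- df[match(lexicon$word, df$word), , drop = FALSE]
  }
  if (anyDuplicated(df$word)) stop("duplicated words in ratings",
                                   call. = FALSE)
  df$self_rating <- as.numeric(df$self_rating)
  df$other_rating <- as.numeric(df$other_rating)
  df$evidence <- evidence(df$self_rating, df$other_rating)
  df <- df[c("word", "self_rating", "other_rating", "evidence")]
  rownames(df) <- NULL
  class(df) <- c("standard_ratings", "data.frame")
  df
}

#' Read or write a standard-ratings file
#'
#' Ratings files are delimited text with a header row and columns `word`,
#' `self_rating`, `other_rating`; ratings are written with two decimal
#' places (the visual-analog scale is continuous).
#'
#' @param path file path.
#' @param lexicon parent lexicon the ratings must cover (checked on read).
#' @param sep field delimiter.
#' @return `read_ratings()` returns a `standard_ratings` object;
#'   `write_ratings()` returns `path` invisibly.
#' @export
read_ratings <- function(path, lexicon = NULL, sep = "\t") {
  if (!file.exists(path)) stop("ratings file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", fileEncoding = "UTF-8")
  as_standard_ratings(df, lexicon)
}

#' @rdname read_ratings
#' @param ratings a `standard_ratings` object.
#' @export
write_ratings <- function(ratings, path, sep = "\t") {
  ratings <- as_standard_ratings(ratings)
  out <- data.frame(word = ratings$word,
                    self_rating = sprintf("%.2f", ratings$self_rating),
                    other_rating = sprintf("%.2f", ratings$other_rating))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
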