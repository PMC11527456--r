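#' Initialize a weighted up-down staircase
#'
#' One staircase per condition moves along the evidence diagonal.  It starts
#' at the median evidence of the words favoring the condition's correct
#' response (positive evidence for the self condition, negative for other)
#' and is capped at the ends of the evidence scale, -100 and 100.  The step
#' size is the range of attainable evidence divided by `step_divisor`; with
#' the theoretical range 200 and the default divisor 20 the step is 10
#' evidence units.
#'
#' @param condition `"self"` or `"other"`.
#' @param ratings a [as_standard_ratings()] object.
#' @param step_divisor divisor of the evidence range (default 20).
#' @param range_mode `"theoretical"` uses the full scale range 200;
#'   `"empirical"` uses the range of this participant's word evidence.
#' @return A `staircase` object: a list with `condition`, `sign` (+1 self,
#'   -1 other), `position`, `step_size`, `up_steps` (the 2-2-3 error cycle)
#'   and `cursor` into that cycle.
#' @export
init_staircase <- function(condition, ratings, step_divisor = 20,
                           range_mode = c("theoretical", "empirical")) {
  condition <- match.arg(condition, c("self", "other"))
  range_mode <- match.arg(range_mode)
  ratings <- as_standard_ratings(ratings)
  sign <- if (condition == "self") 1 else -1
  favoring <- ratings$evidence[sign * ratings$evidence > 0]
  if (length(favoring) == 0L) {
    stop("no words favor the ", condition, " condition; cannot start its ",
         "staircase", call. = FALSE)
  }
  range_e <- switch(range_mode,
                    theoretical = 200,
                    empirical = diff(range(ratings$evidence)))
  state <- list(condition = condition, sign = sign,
                position = stats::median(favoring),
                step_size = range_e / step_divisor,
                up_steps = c(2, 2, 3), cursor = 1L)
  class(state) <- "staircase"
  state
}

#' Move a staircase after a response
#'
#' After a correct response the staircase moves one step in the direction
#' favoring the incorrect response (making the next trial harder); after an
#' error it moves 2, 2 or 3 steps -- cycling in that order, the cycle
#' advancing only on errors -- toward the condition's correct response.
#' The position is clamped to \[-100, 100\].  This 1-down / mean-2.33-up
#' weighting equilibrates at 70% correct (see [equilibrium_accuracy()]).
#'
#' @param object a `staircase` object.
#' @param correct logical, whether the response was correct.
#' @param ... unused.
#' @return The updated `staircase` object.
#' @export
update.staircase <- function(object, correct, ...) {
  stopifnot(is.logical(correct), length(correct) == 1L, !is.na(correct))
  if (correct) {
    object$position <- object$position - object$sign * object$step_size
  } else {
    k <- object$up_steps[object$cursor]
    object$position <- object$position + object$sign * k * object$step_size
    object$cursor <- if (object$cursor == length(object$up_steps)) 1L else
      object$cursor + 1L
  }
  object$position <- min(max(object$position, -100), 100)
  object
}

#' Equilibrium accuracy of a weighted up-down staircase
#'
#' The accuracy at which the expected staircase movement is zero: with
#' `d` steps down after a correct response and an average of `u` steps up
#' after an error, `p * d = (1 - p) * u`, so `p = u / (u + d)`.  For the
#' 1-down / (2,2,3)-up rule this is (7/3) / (7/3 + 1) = 0.7.
#'
#' @param down_steps steps moved after a correct response (default 1).
#' @param up_steps numeric vector of the cycling error steps (default
#'   `c(2, 2, 3)`).
#' @return The equilibrium proportion correct.
#' @export
equilibrium_accuracy <- function(down_steps = 1, up_steps = c(2, 2, 3)) {
  if (down_steps <= 0 || any(up_steps <= 0)) {
    stop("staircase steps must be positive", call. = FALSE)
  }
  u <- mean(up_steps)
  u / (u + down_steps)
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf("<staircase> condition=%s position=%.2f step=%.2f cycle=%s cursor=%d\n",
              x$condition, x$position, x$step_size,
              paste(x$up_steps, collapse = "-"), x$cursor))
  invisible(x)
}
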