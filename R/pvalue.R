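#' Exact p-value calibration of PWM scores
#'
#' Computes the exact null distribution of the (discretized) log-odds score of
#' a random word drawn from the background model, by per-position convolution
#' (dynamic programming). Scores are discretized by mapping each position's
#' log-odds entries to integers on a grid of step
#' `delta = max(per-position score range) / granularity`, so the total
#' discretization error is bounded by `width * delta` bits of score. The
#' p-value of a score is the tail probability `P(score >= s)` under the
#' background, reported at the floor of the discretized grid; the reported
#' value can deviate from the exact tail only within the `width * delta`
#' score neighbourhood of `s` (half a bin per position), and is exact on the
#' integer grid itself.
#'
#' @param pwm A `pwm`.
#' @param background A `background`.
#' @param granularity Number of discretization bins per position score range
#'   (minimum 100; default 1000).
#' @return A `pvalue_table` object holding the log-odds matrix, its integer
#'   discretization, and the exact tail distribution over the integer score
#'   support.
#' @export
score_pvalue_table <- function(pwm, background = make_background(),
                               granularity = 1000L) {
  if (granularity < 100L) stop("granularity must be at least 100")
  lo <- log_odds(pwm, background)
  w <- nrow(lo)
  row_min <- apply(lo, 1L, min)
  row_max <- apply(lo, 1L, max)
  delta <- max(row_max - row_min) / granularity
  if (delta <= 0) delta <- 1 # degenerate: all entries equal
  int_mat <- matrix(as.integer(round((lo - row_min) / delta)), nrow = w)
  colnames(int_mat) <- DNA_BASES

  # convolution over positions: prob[k + 1] = P(integer score == k)
  prob <- 1
  bg <- background$freqs
  for (i in seq_len(w)) {
    top <- max(int_mat[i, ])
    new <- numeric(length(prob) + top)
    for (b in seq_len(4L)) {
      s <- int_mat[i, b]
      idx <- seq_along(prob) + s
      new[idx] <- new[idx] + bg[b] * prob
    }
    prob <- new
  }
  tail <- rev(cumsum(rev(prob)))
  tail <- pmin(tail, 1)

  structure(
    list(name = pwm$name, width = w, lo = lo, int_mat = int_mat,
         delta = delta, offset = sum(row_min), prob = prob, tail = tail,
         granularity = as.integer(granularity), background = background),
    class = "pvalue_table"
  )
}

#' @export
print.pvalue_table <- function(x, ...) {
  cat("p-value table for PWM '", x$name, "': width ", x$width,
      ", granularity ", x$granularity, "\n", sep = "")
  cat(sprintf("score support [%.3f, %.3f] bits; p(max score) = %.3g\n",
              x$offset, x$offset + (length(x$tail) - 1L) * x$delta,
              x$tail[length(x$tail)]))
  invisible(x)
}

# integer score of each word of a coded sequence laid out as a matrix of
# codes (rows = words); NA codes propagate
word_int_scores <- function(code_mat, int_mat) {
  s <- int_mat[1L, ][code_mat[, 1L]]
  for (j in seq_len(ncol(code_mat))[-1L]) {
    s <- s + int_mat[j, ][code_mat[, j]]
  }
  s
}

#' Calibrated p-value of a log-odds score
#'
#' @param table A `pvalue_table` from [score_pvalue_table()].
#' @param score Numeric vector of log-odds scores in bits.
#' @return The conservative (discretized-floor) tail probability
#'   `P(random word score >= score)` for each input score.
#' @export
pwm_pvalue <- function(table, score) {
  k <- floor((score - table$offset) / table$delta)
  k <- pmin(pmax(k, 0), length(table$tail) - 1L)
  unname(table$tail[k + 1L])
}

# smallest integer score whose tail probability is <= p, or NA if none
min_int_score_for_p <- function(table, p) {
  ok <- which(table$tail <= p)
  if (!length(ok)) return(NA_integer_)
  ok[1L] - 1L
}
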