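#' Scan sequences for PWM matches
#'
#' Slides a PWM over every window of each contig (both strands by default) and
#' reports windows whose calibrated p-value is at or below `p_threshold`.
#' Coordinates are 0-based half-open on the forward strand; minus-strand hits
#' report forward-strand coordinates with `strand = "-"` and `matched_seq`
#' reverse-complemented into motif orientation. Windows containing any
#' non-ACGT character are skipped, never scored. All hits above threshold are
#' reported, including overlapping ones; overlap resolution is left to
#' downstream stages so that the scanner stays a pure function of its inputs.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector of
#'   contig sequences.
#' @param pwm A `pwm`.
#' @param background A `background`, or `NULL` to estimate a 0-order
#'   composition from the scanned assembly (pooled contigs), which is the
#'   default and matches common practice on AT-rich yeast genomes.
#' @param p_threshold Hit threshold on the calibrated p-value, in (0, 1).
#' @param strands `"both"` or `"forward"`.
#' @param pvalue_table Optional precomputed [score_pvalue_table()] for `pwm`
#'   and `background` (computed internally when `NULL`).
#' @return A `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `score` (log-odds, bits), `p_value`, `matched_seq`, sorted by
#'   `(contig, start)`.
#' @export
scan_genome <- function(genome, pwm, background = NULL, p_threshold = 1e-4,
                        strands = c("both", "forward"), pvalue_table = NULL) {
  strands <- match.arg(strands)
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  contigs <- as_contig_vector(genome)
  if (is.null(background)) background <- estimate_background(contigs)
  if (is.null(pvalue_table)) {
    pvalue_table <- score_pvalue_table(pwm, background)
  }
  hits <- lapply(names(contigs), function(ctg) {
    scan_contig(contigs[[ctg]], ctg, pwm, pvalue_table, p_threshold, strands)
  })
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0L) return(empty_hits())
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), p_value = numeric(),
             matched_seq = character(), stringsAsFactors = FALSE)
}

scan_contig <- function(seq, contig, pwm, table, p_threshold, strands) {
  w <- pwm$width
  L <- nchar(seq)
  if (L < w) return(empty_hits())
  k_min <- min_int_score_for_p(table, p_threshold)
  if (is.na(k_min)) return(empty_hits())

  fwd <- scan_strand(seq, table, k_min)
  res <- list()
  if (length(fwd$pos)) {
    res$f <- data.frame(
      contig = contig, start = fwd$pos, end = fwd$pos + w, strand = "+",
      score = fwd$score, p_value = fwd$p,
      matched_seq = substring(seq, fwd$pos + 1L, fwd$pos + w),
      stringsAsFactors = FALSE)
  }
  if (strands == "both") {
    rc <- revcomp(seq)
    rev <- scan_strand(rc, table, k_min)
    if (length(rev$pos)) {
      res$r <- data.frame(
        contig = contig, start = L - rev$pos - w, end = L - rev$pos,
        strand = "-", score = rev$score, p_value = rev$p,
        matched_seq = substring(rc, rev$pos + 1L, rev$pos + w),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_hits())
  do.call(rbind, res)
}

# returns 0-based window start offsets on the given strand's sequence, with
# real scores and calibrated p-values, for integer scores >= k_min
scan_strand <- function(seq, table, k_min) {
  w <- table$width
  codes <- seq_codes(seq)
  n <- length(codes) - w + 1L
  if (n < 1L) return(list(pos = integer(), score = numeric(), p = numeric()))
  int_mat <- table$int_mat
  s <- int_mat[1L, ][codes[seq_len(n)]]
  for (j in seq_len(w)[-1L]) {
    s <- s + int_mat[j, ][codes[j:(j + n - 1L)]]
  }
  keep <- which(!is.na(s) & s >= k_min)
  if (!length(keep)) return(list(pos = integer(), score = numeric(), p = numeric()))
  # exact real scores for the (few) hits only
  lo <- table$lo
  score <- vapply(keep, function(i) {
    sum(lo[cbind(seq_len(w), codes[i:(i + w - 1L)])])
  }, numeric(1))
  list(pos = keep - 1L, score = score, p = unname(table$tail[s[keep] + 1L]))
}
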