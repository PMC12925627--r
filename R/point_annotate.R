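#' Extract candidate centromere windows around CDEIII hits
#'
#' Scans the assembly on both strands with the CDEIII PWM and, for every hit
#' with at least `upstream` bp of sequence available on the CDEI side, returns
#' a fixed-length candidate window consisting of the upstream stretch followed
#' by the motif (224 + 26 = 250 bp with the defaults). Windows are reported in
#' centromere orientation: for minus-strand hits, "upstream" lies downstream
#' on the forward strand and the window sequence is reverse-complemented, so
#' the CDEIII motif always occupies the window's 3' end. Hits too close to a
#' contig edge are dropped; their count is attached as attribute
#' `"edge_dropped"` and reported as a message.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param cdeiii CDEIII `pwm` (typically 26 bp).
#' @param p_threshold CDEIII hit threshold; practical values range from 1e-3
#'   (sensitive) to 1e-7 (strict), tuned per clade. Default 1e-5.
#' @param background `background`, or `NULL` to estimate from the assembly.
#' @param upstream Upstream window length in bp (default 224).
#' @return A `data.frame` of candidate windows with forward-strand window
#'   coordinates (0-based half-open), orientation, the window sequence in
#'   centromere orientation, and the CDEIII hit's coordinates, score and
#'   p-value.
#' @export
extract_windows <- function(genome, cdeiii, p_threshold = 1e-5,
                            background = NULL, upstream = 224L) {
  contigs <- as_contig_vector(genome)
  if (is.null(background)) background <- estimate_background(contigs)
  hits <- scan_genome(contigs, cdeiii, background, p_threshold,
                      strands = "both")
  lens <- setNames(nchar(contigs), names(contigs))
  w3 <- cdeiii$width

  out <- data.frame(contig = character(), window_start = integer(),
                    window_end = integer(), orientation = character(),
                    window_seq = character(), cdeiii_start = integer(),
                    cdeiii_end = integer(), cdeiii_score = numeric(),
                    cdeiii_p = numeric(), stringsAsFactors = FALSE)
  dropped <- 0L
  if (nrow(hits)) {
    rows <- vector("list", nrow(hits))
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      L <- lens[[h$contig]]
      if (h$strand == "+") {
        ws <- h$start - upstream
        we <- h$end
        if (ws < 0L) { dropped <- dropped + 1L; next }
        seq <- substring(contigs[[h$contig]], ws + 1L, we)
      } else {
        ws <- h$start
        we <- h$end + upstream
        if (we > L) { dropped <- dropped + 1L; next }
        seq <- revcomp(substring(contigs[[h$contig]], ws + 1L, we))
      }
      rows[[i]] <- data.frame(
        contig = h$contig, window_start = ws, window_end = we,
        orientation = h$strand, window_seq = seq,
        cdeiii_start = h$start, cdeiii_end = h$end,
        cdeiii_score = h$score, cdeiii_p = h$p_value,
        stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) out <- do.call(rbind, rows)
  }
  if (dropped > 0L) {
    message(dropped, " CDEIII hit(s) dropped: fewer than ", upstream,
            " bp available on the CDEI side")
  }
  rownames(out) <- NULL
  stopifnot(all(nchar(out$window_seq) == upstream + w3))
  attr(out, "edge_dropped") <- dropped
  out
}

#' Locate CDEI inside candidate windows and assemble centromere calls
#'
#' Each candidate window (in centromere orientation) is rescanned with the
#' CDEI PWM in the forward orientation only, at a deliberately permissive
#' threshold (default 1e-2). Only placements whose motif lies entirely within
#' the upstream stretch (i.e. not overlapping CDEIII) are considered. Among
#' the qualifying hits, the one maximizing the call's combined-score
#' contribution -- `w2 * score / max_score + w3 * implied_CDEII_AT / 100` --
#' is used, with ties broken towards the window 5' end; this reduces to the
#' best-scoring hit whenever the AT term does not reverse the ordering, and
#' protects the true site against same-score chance hits elsewhere in the
#' AT-poor part of the window. Windows with no qualifying hit are dropped.
#' CDEII is the subsequence strictly between the CDEI end and the CDEIII
#' start; its length and AT content (ambiguous bases excluded) are computed
#' per call.
#'
#' @param windows Output of [extract_windows()].
#' @param cdei CDEI `pwm` (typically 8 bp).
#' @param p_threshold CDEI threshold (default 1e-2).
#' @param background `background` used for CDEI scoring (default uniform).
#' @param weights Combined-score weights `(w1, w2, w3)`; only the CDEI and
#'   AT weights act at this stage.
#' @return A `data.frame` of centromere calls with forward-strand coordinates
#'   of the full CDEI..CDEIII span and of each element, the element
#'   subsequences in centromere orientation, CDEII length and AT percentage,
#'   and the two motif scores.
#' @export
attach_cdei <- function(windows, cdei, p_threshold = 1e-2,
                        background = make_background(),
                        weights = c(1, 1, 1)) {
  table <- score_pvalue_table(cdei, background)
  max_cdei <- max_log_odds_score(cdei, background)
  w1 <- cdei$width
  calls <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    win <- windows[i, ]
    wlen <- nchar(win$window_seq)
    w3 <- win$cdeiii_end - win$cdeiii_start
    upstream <- wlen - w3
    hits <- scan_genome(setNames(win$window_seq, "w"), cdei, background,
                        p_threshold, strands = "forward",
                        pvalue_table = table)
    hits <- hits[hits$end <= upstream, , drop = FALSE]
    if (!nrow(hits)) next
    implied_at <- vapply(hits$end, function(e) {
      at_percent(substring(win$window_seq, e + 1L, upstream))
    }, numeric(1))
    implied_at[is.na(implied_at)] <- 0
    objective <- weights[2L] * hits$score / max_cdei +
      weights[3L] * implied_at / 100
    hits <- hits[order(-objective, hits$start), , drop = FALSE]
    h <- hits[1L, ]

    cdei_seq <- h$matched_seq
    cdeii_seq <- substring(win$window_seq, h$end + 1L, upstream)
    cdeiii_seq <- substring(win$window_seq, upstream + 1L, wlen)
    full_seq <- substring(win$window_seq, h$start + 1L, wlen)

    if (win$orientation == "+") {
      start <- win$window_start + h$start
      end <- win$window_end
      cdei_start <- start; cdei_end <- start + w1
      cdeiii_start <- win$cdeiii_start; cdeiii_end <- win$cdeiii_end
    } else {
      start <- win$window_start
      end <- win$window_end - h$start
      cdei_end <- end; cdei_start <- end - w1
      cdeiii_start <- win$cdeiii_start; cdeiii_end <- win$cdeiii_end
    }
    if (win$orientation == "+") {
      cdeii_start <- cdei_end; cdeii_end <- cdeiii_start
    } else {
      cdeii_start <- cdeiii_end; cdeii_end <- cdei_start
    }

    calls[[i]] <- data.frame(
      contig = win$contig, start = start, end = end,
      orientation = win$orientation, full_seq = full_seq,
      cdei_seq = cdei_seq, cdeii_seq = cdeii_seq, cdeiii_seq = cdeiii_seq,
      cdei_start = cdei_start, cdei_end = cdei_end,
      cdeii_start = cdeii_start, cdeii_end = cdeii_end,
      cdeiii_start = cdeiii_start, cdeiii_end = cdeiii_end,
      cdeii_length = nchar(cdeii_seq), cdeii_at = at_percent(cdeii_seq),
      score_cdei = h$score, score_cdeiii = win$cdeiii_score,
      stringsAsFactors = FALSE)
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty_calls())
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             orientation = character(), full_seq = character(),
             cdei_seq = character(), cdeii_seq = character(),
             cdeiii_seq = character(), cdei_start = integer(),
             cdei_end = integer(), cdeii_start = integer(),
             cdeii_end = integer(), cdeiii_start = integer(),
             cdeiii_end = integer(), cdeii_length = integer(),
             cdeii_at = numeric(), score_cdei = numeric(),
             score_cdeiii = numeric(), stringsAsFactors = FALSE)
}

#' Combined candidate score
#'
#' A max-normalized weighted sum of the two motif scores and the CDEII AT
#' percentage:
#' `w1 * score_cdeiii / max_cdeiii + w2 * score_cdei / max_cdei + w3 * at / 100`,
#' with default weights (1, 1, 1). The formula is scale-free and strictly
#' increasing in each component; a perfect-consensus call with a 100% AT CDEII
#' scores `w1 + w2 + w3`.
#'
#' @param calls Calls from [attach_cdei()].
#' @param max_cdei,max_cdeiii Maximum achievable log-odds scores of the two
#'   PWMs under the backgrounds used for scanning (see
#'   [max_log_odds_score()]).
#' @param weights Numeric length-3 vector `(w1, w2, w3)` for CDEIII score,
#'   CDEI score and CDEII AT.
#' @return Numeric vector of combined scores.
#' @export
combined_score <- function(calls, max_cdei, max_cdeiii, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, max_cdei > 0, max_cdeiii > 0)
  weights[1L] * calls$score_cdeiii / max_cdeiii +
    weights[2L] * calls$score_cdei / max_cdei +
    weights[3L] * calls$cdeii_at / 100
}

#' Rule-based filter cascade over centromere candidates
#'
#' Applies, in order: (1) keep only the `top_n` candidates by combined score;
#' (2) compute the median CDEII length of the top 5 survivors by score and
#' remove candidates whose length differs from it by more than `length_tol`;
#' (3) remove candidates with CDEII AT content below `min_at` percent;
#' (4) remove duplicates -- identical full sequences, or calls overlapping by
#' more than `overlap_frac` of the shorter call on the same contig and
#' orientation (small contigs of fragmented assemblies often carry copies),
#' keeping the higher combined score (ties: lexicographically smaller
#' (contig, start)); (5) recompute the median CDEII length and AT over the
#' survivors and remove candidates for which BOTH the length lies outside
#' median +/- `joint_length_tol` AND the AT content is below
#' median AT - `joint_at_delta`. Every input row is returned with its
#' `status` set to `"retained"` or `"removed:<rule>"`.
#'
#' @param calls Calls carrying a `combined_score` column.
#' @param top_n,length_tol,min_at,joint_length_tol,joint_at_delta,overlap_frac
#'   Cascade parameters; defaults 50, 30, 70, 10, 7, 0.5.
#' @return `calls` with a `status` column; row order preserved.
#' @export
filter_cascade <- function(calls, top_n = 50L, length_tol = 30,
                           min_at = 70, joint_length_tol = 10,
                           joint_at_delta = 7, overlap_frac = 0.5) {
  if (!nrow(calls)) {
    calls$status <- character(0)
    return(calls)
  }
  stopifnot("combined_score" %in% names(calls))
  status <- rep("retained", nrow(calls))
  alive <- function() which(status == "retained")

  # rule 1: top N by combined score
  ord <- order(-calls$combined_score, calls$contig, calls$start)
  if (length(ord) > top_n) status[ord[-seq_len(top_n)]] <- "removed:top50"

  # rule 2: CDEII length vs median of the top 5 survivors by score
  a <- alive()
  if (length(a)) {
    top5 <- a[order(-calls$combined_score[a], calls$contig[a],
                    calls$start[a])][seq_len(min(5L, length(a)))]
    m5 <- median(calls$cdeii_length[top5])
    bad <- a[abs(calls$cdeii_length[a] - m5) > length_tol]
    status[bad] <- "removed:cdeii_length"
  }

  # rule 3: low AT content
  a <- alive()
  bad <- a[is.na(calls$cdeii_at[a]) | calls$cdeii_at[a] < min_at]
  status[bad] <- "removed:at_content"

  # rule 4: duplicates
  a <- alive()
  if (length(a) > 1L) {
    pref <- order(-calls$combined_score[a], calls$contig[a], calls$start[a])
    kept <- integer(0)
    for (idx in a[pref]) {
      dup <- FALSE
      for (k in kept) {
        if (calls$full_seq[idx] == calls$full_seq[k]) { dup <- TRUE; break }
        if (calls$contig[idx] == calls$contig[k] &&
            calls$orientation[idx] == calls$orientation[k]) {
          ov <- min(calls$end[idx], calls$end[k]) -
            max(calls$start[idx], calls$start[k])
          shorter <- min(calls$end[idx] - calls$start[idx],
                         calls$end[k] - calls$start[k])
          if (ov > overlap_frac * shorter) { dup <- TRUE; break }
        }
      }
      if (dup) status[idx] <- "removed:duplicate" else kept <- c(kept, idx)
    }
  }

  # rule 5: joint length/AT outliers vs survivor medians (strict AND)
  a <- alive()
  if (length(a)) {
    med_len <- median(calls$cdeii_length[a])
    med_at <- median(calls$cdeii_at[a])
    bad <- a[abs(calls$cdeii_length[a] - med_len) > joint_length_tol &
               calls$cdeii_at[a] < med_at - joint_at_delta]
    status[bad] <- "removed:joint_length_at"
  }

  calls$status <- status
  calls
}

#' Annotate point centromeres in a genome assembly
#'
#' End-to-end two-stage pipeline: CDEIII scan and window extraction
#' ([extract_windows()]), CDEI rescan and CDEII measurement
#' ([attach_cdei()]), combined scoring ([combined_score()]) and the filter
#' cascade ([filter_cascade()]). The number of retained calls is the inferred
#' karyotype. Deterministic: the same inputs always give byte-identical
#' output.
#'
#' @inheritParams extract_windows
#' @param cdei CDEI `pwm`.
#' @param p_cdeiii,p_cdei Stage thresholds (defaults 1e-5 and 1e-2).
#' @param weights Combined-score weights, see [combined_score()].
#' @param cascade Named list overriding [filter_cascade()] parameters.
#' @return An object of class `cen_annotation`: a list with `calls` (all
#'   candidates with `status`), `retained` (the retained subset), `karyotype`
#'   (retained count), `background`, `genome_size`, and `edge_dropped`.
#' @export
annotate_point_centromeres <- function(genome, cdei, cdeiii,
                                       p_cdeiii = 1e-5, p_cdei = 1e-2,
                                       background = NULL,
                                       weights = c(1, 1, 1),
                                       cascade = list(), upstream = 224L) {
  contigs <- as_contig_vector(genome)
  if (is.null(background)) background <- estimate_background(contigs)
  windows <- extract_windows(contigs, cdeiii, p_cdeiii, background, upstream)
  calls <- attach_cdei(windows, cdei, p_cdei, background, weights)
  if (nrow(calls)) {
    calls$combined_score <- combined_score(
      calls,
      max_cdei = max_log_odds_score(cdei, background),
      max_cdeiii = max_log_odds_score(cdeiii, background),
      weights = weights)
    calls <- do.call(filter_cascade, c(list(calls = calls), cascade))
  } else {
    calls$combined_score <- numeric(0)
    calls$status <- character(0)
  }
  retained <- calls[calls$status == "retained", , drop = FALSE]
  retained <- retained[order(retained$contig, retained$start), , drop = FALSE]
  rownames(retained) <- NULL
  structure(
    list(calls = calls, retained = retained, karyotype = nrow(retained),
         background = background, genome_size = sum(nchar(contigs)),
         edge_dropped = attr(windows, "edge_dropped")),
    class = "cen_annotation")
}

#' @export
print.cen_annotation <- function(x, ...) {
  cat("point-centromere annotation: ", nrow(x$calls), " candidate(s), ",
      x$karyotype, " retained (inferred karyotype)\n", sep = "")
  if (x$karyotype > 0) {
    cat(sprintf("CDEII length median %.0f bp, AT median %.1f%%\n",
                median(x$retained$cdeii_length), median(x$retained$cdeii_at)))
  }
  invisible(x)
}

#' Inferred karyotype (retained centromere count)
#'
#' @param annotation A `cen_annotation` from [annotate_point_centromeres()]
#'   or a `core_annotation` from [annotate_core_centromeres()].
#' @return Integer chromosome-number estimate.
#' @export
karyotype <- function(annotation) {
  annotation$karyotype
}
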