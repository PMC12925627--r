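#' Scan for core-centromere motifs and extract downstream sequence
#'
#' Single-motif search for Mucoromycota-style core centromeres: each hit of
#' the (typically 41-bp) motif is reported together with up to
#' `downstream` bp of sequence 3' of the motif in motif orientation. For
#' minus-strand hits "downstream" lies 5' of the motif on the forward strand
#' and is reverse-complemented. Core-centromere contigs are often short
#' (flanking retrotransposons fragment assemblies), so the downstream stretch
#' is truncated at the contig edge and flagged.
#'
#' @inheritParams scan_genome
#' @param motif Core-centromere `pwm` (41 bp by default conventions).
#' @param downstream Downstream length to extract, in bp (default 750).
#' @return A `data.frame` with one row per motif hit: hit coordinates,
#'   strand, score and p-value, `downstream_seq`, `downstream_length` and a
#'   `truncated` flag.
#' @export
scan_core_motif <- function(genome, motif, p_threshold = 1e-5,
                            background = NULL, downstream = 750L) {
  contigs <- as_contig_vector(genome)
  if (is.null(background)) background <- estimate_background(contigs)
  hits <- scan_genome(contigs, motif, background, p_threshold,
                      strands = "both")
  if (!nrow(hits)) {
    hits$downstream_seq <- character(0)
    hits$downstream_length <- integer(0)
    hits$truncated <- logical(0)
    return(hits)
  }
  lens <- setNames(nchar(contigs), names(contigs))
  down <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    L <- lens[[h$contig]]
    if (h$strand == "+") {
      down[i] <- substring(contigs[[h$contig]], h$end + 1L,
                           min(h$end + downstream, L))
    } else {
      from <- max(h$start - downstream, 0L)
      down[i] <- revcomp(substring(contigs[[h$contig]], from + 1L, h$start))
    }
  }
  hits$downstream_seq <- down
  hits$downstream_length <- nchar(down)
  hits$truncated <- hits$downstream_length < downstream
  if (any(hits$truncated)) {
    message(sum(hits$truncated), " hit(s) with downstream sequence truncated ",
            "at a contig edge")
  }
  hits
}

#' GC content in a moving window
#'
#' @param seq A DNA string.
#' @param window Window size in bp (default 100).
#' @param step Step between window starts in bp (default 1).
#' @return A `data.frame` with the 0-based window start `offset` and
#'   `gc_percent` = 100 * (G+C) / (window - ambiguous). Windows with more
#'   than 50% ambiguous bases are omitted; a sequence shorter than `window`
#'   yields an empty profile.
#' @export
gc_moving_window <- function(seq, window = 100L, step = 1L) {
  stopifnot(window >= 1L, step >= 1L)
  codes <- seq_codes(seq)
  L <- length(codes)
  if (L < window) {
    return(data.frame(offset = integer(), gc_percent = numeric()))
  }
  is_gc <- as.integer(!is.na(codes) & (codes == 2L | codes == 3L))
  is_amb <- as.integer(is.na(codes))
  cg <- c(0L, cumsum(is_gc))
  ca <- c(0L, cumsum(is_amb))
  offsets <- seq.int(0L, L - window, by = step)
  gc <- cg[offsets + window + 1L] - cg[offsets + 1L]
  amb <- ca[offsets + window + 1L] - ca[offsets + 1L]
  keep <- amb <= window / 2
  data.frame(offset = offsets[keep],
             gc_percent = 100 * gc[keep] / (window - amb[keep]))
}

#' Estimate the length of the AT-rich region downstream of a core motif
#'
#' Takes the maximal contiguous run of moving-window positions starting at
#' offset 0 whose GC content is at or below `gc_cutoff_percent`, and reports
#' `(number of run windows - 1) * step + window` bp, capped at the
#' downstream-sequence length. The run is broken by the first window above
#' the cutoff or missing from the profile. Returns 0 when the first window
#' already exceeds the cutoff or when fewer than `min_run_windows` windows
#' qualify. The cutoff replaces the by-eye identification of AT-rich tracts
#' in GC profile plots with an explicit, testable rule.
#'
#' @param gc_profile Profile from [gc_moving_window()] (computed with the
#'   same `window`/`step`).
#' @param downstream_length Length of the profiled downstream sequence, bp.
#' @param gc_cutoff_percent GC threshold in percent (default 25).
#' @param min_run_windows Minimum qualifying run length in windows (default 1).
#' @param window,step Parameters the profile was computed with.
#' @return Estimated AT-region length in bp (integer, possibly 0).
#' @export
estimate_at_region <- function(gc_profile, downstream_length,
                               gc_cutoff_percent = 25, min_run_windows = 1L,
                               window = 100L, step = 1L) {
  if (!nrow(gc_profile)) return(0L)
  run <- 0L
  repeat {
    off <- run * step
    j <- match(off, gc_profile$offset)
    if (is.na(j) || gc_profile$gc_percent[j] > gc_cutoff_percent) break
    run <- run + 1L
    if (run * step > max(gc_profile$offset)) break
  }
  if (run < min_run_windows || run == 0L) return(0L)
  min(as.integer((run - 1L) * step + window), as.integer(downstream_length))
}

#' Annotate Mucoromycota-style core centromeres
#'
#' Composes [scan_core_motif()], [gc_moving_window()] and
#' [estimate_at_region()]: one motif search, extraction of up to 750 bp
#' downstream, GC profiling in 100-bp moving windows, and an explicit
#' AT-region length estimate per call. Also reports the AT content of the
#' first 100 bp downstream of the motif.
#'
#' @inheritParams scan_core_motif
#' @param window,step GC moving-window parameters (defaults 100 and 1).
#' @param gc_cutoff_percent AT-region GC cutoff (default 25).
#' @param min_at_region Minimum AT-region length (bp) for a call to count as
#'   a bona fide core centromere (default one window, 100 bp); this is the
#'   explicit stand-in for identifying real cores by eye from GC profiles,
#'   and rejects chance motif hits in ordinary sequence.
#' @return A `core_annotation` object: list with `calls` (data frame with
#'   motif hit, `at100_downstream`, `at_region_length`, `truncated`,
#'   `bona_fide`), `karyotype` (bona fide call count), `background` and
#'   `genome_size`.
#' @export
annotate_core_centromeres <- function(genome, motif, p_threshold = 1e-5,
                                      background = NULL, downstream = 750L,
                                      window = 100L, step = 1L,
                                      gc_cutoff_percent = 25,
                                      min_at_region = 100L) {
  contigs <- as_contig_vector(genome)
  if (is.null(background)) background <- estimate_background(contigs)
  calls <- scan_core_motif(contigs, motif, p_threshold, background, downstream)
  n <- nrow(calls)
  at100 <- numeric(n)
  at_len <- integer(n)
  for (i in seq_len(n)) {
    ds <- calls$downstream_seq[i]
    at100[i] <- at_percent(substring(ds, 1L, min(100L, nchar(ds))))
    prof <- gc_moving_window(ds, window = window, step = step)
    at_len[i] <- estimate_at_region(prof, nchar(ds),
                                    gc_cutoff_percent = gc_cutoff_percent,
                                    window = window, step = step)
  }
  calls$at100_downstream <- at100
  calls$at_region_length <- at_len
  calls$bona_fide <- at_len >= min_at_region
  structure(
    list(calls = calls, karyotype = sum(calls$bona_fide),
         background = background, genome_size = sum(nchar(contigs))),
    class = "core_annotation")
}

#' @export
print.core_annotation <- function(x, ...) {
  cat("core-centromere annotation: ", nrow(x$calls), " motif hit(s), ",
      x$karyotype, " bona fide call(s)\n", sep = "")
  bf <- x$calls[x$calls$bona_fide, , drop = FALSE]
  if (nrow(bf)) {
    cat(sprintf("AT-region length median %.0f bp (range %d-%d)\n",
                median(bf$at_region_length), min(bf$at_region_length),
                max(bf$at_region_length)))
  }
  invisible(x)
}

#' Iteratively refine a core-centromere search motif
#'
#' Rebuilds the PWM from the matched sites of the current hit set and
#' rescans, until the hit set (contig, start, strand) no longer changes or
#' `max_iter` is reached. This is the in-silico analogue of progressively
#' updating search motifs with newly discovered centromere sequences until no
#' additional loci are found.
#'
#' @inheritParams scan_core_motif
#' @param pseudocount Pseudocount for the rebuilt PWMs.
#' @param max_iter Maximum refinement rounds (default 10).
#' @return List with the final `pwm`, final `hits`, number of `iterations`,
#'   and a `converged` flag.
#' @export
refine_core_motif <- function(genome, motif, p_threshold = 1e-5,
                              background = NULL, pseudocount = 0.1,
                              max_iter = 10L) {
  contigs <- as_contig_vector(genome)
  if (is.null(background)) background <- estimate_background(contigs)
  key <- function(h) paste(h$contig, h$start, h$strand, sep = ":")
  hits <- scan_genome(contigs, motif, background, p_threshold)
  pwm <- motif
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (!nrow(hits)) break
    pwm <- build_pwm(hits$matched_seq, pseudocount = pseudocount,
                     name = motif$name)
    new_hits <- scan_genome(contigs, pwm, background, p_threshold)
    if (setequal(key(new_hits), key(hits))) {
      hits <- new_hits
      converged <- TRUE
      break
    }
    hits <- new_hits
  }
  list(pwm = pwm, hits = hits, iterations = iter, converged = converged)
}
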