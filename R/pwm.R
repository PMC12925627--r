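#' Position weight matrices
#'
#' A `pwm` is a per-position nucleotide probability model of a DNA motif: a
#' `width x 4` matrix of probabilities over A, C, G, T, one row per motif
#' position. It is the searchable representation of centromere motifs such as
#' the ~8-bp CDEI and ~26-bp CDEIII elements of budding-yeast point
#' centromeres, or the ~41-bp Mucoromycota core-centromere motif.
#'
#' @name pwm
NULL

new_pwm <- function(probs, name = "motif", pseudocount = 0, n_sites = 0L) {
  probs <- as.matrix(probs)
  colnames(probs) <- DNA_BASES
  rownames(probs) <- NULL
  x <- structure(
    list(name = name, width = nrow(probs), probs = probs,
         pseudocount = pseudocount, n_sites = as.integer(n_sites)),
    class = "pwm"
  )
  validate_pwm(x)
  x
}

validate_pwm <- function(x) {
  stopifnot(is.matrix(x$probs), ncol(x$probs) == 4L, x$width >= 1L)
  sums <- rowSums(x$probs)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("pwm '", x$name, "': row ", which(abs(sums - 1) > 1e-9)[1L],
         " does not sum to 1")
  }
  if (x$pseudocount > 0 && any(x$probs <= 0)) {
    stop("pwm '", x$name, "': non-positive probability despite pseudocount > 0")
  }
  invisible(x)
}

#' Build a PWM from aligned example sites
#'
#' Tallies base frequencies at each position of a set of equal-length aligned
#' sites and converts them to probabilities with additive (pseudocount)
#' smoothing against a uniform base composition:
#' `probs[i, b] = (count(b at i) + pseudocount * 0.25) / (n_sites + pseudocount)`.
#' An `N` in a site contributes 0.25 to each base's count at that position.
#'
#' @param sites Character vector of equal-length DNA strings (alphabet ACGTN).
#' @param pseudocount Non-negative smoothing mass; the default 0.1 follows the
#'   MEME convention of small additive smoothing and keeps all log-odds finite
#'   even for consensus-only site sets.
#' @param name Motif name carried through to hits and file output.
#' @return A `pwm` object.
#' @examples
#' build_pwm(c("ACGT", "ACGA"), pseudocount = 0)$probs
#' @export
build_pwm <- function(sites, pseudocount = 0.1, name = "motif") {
  if (length(sites) == 0L) stop("no sites given")
  sites <- toupper(sites)
  w <- nchar(sites[1L])
  bad <- which(nchar(sites) != w)
  if (length(bad)) {
    stop("site ", bad[1L], " ('", sites[bad[1L]], "') has length ",
         nchar(sites[bad[1L]]), ", expected ", w)
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  chars <- matrix(unlist(strsplit(sites, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(sites), byrow = TRUE)
  if (!all(chars %in% c(DNA_BASES, "N"))) {
    stop("sites may only contain A, C, G, T or N")
  }
  counts <- matrix(0, nrow = w, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  for (b in seq_len(4L)) counts[, b] <- colSums(chars == DNA_BASES[b])
  n_count <- colSums(chars == "N")
  counts <- counts + 0.25 * n_count
  probs <- (counts + pseudocount * 0.25) / (length(sites) + pseudocount)
  new_pwm(probs, name = name, pseudocount = pseudocount,
          n_sites = length(sites))
}

#' Build a PWM from a consensus string
#'
#' Each position assigns probability `identity` to the consensus base and
#' `(1 - identity) / 3` to the other three bases; this is the PWM implied by a
#' per-position substitution model at rate `1 - identity`, and matches the
#' noise model of the synthetic-genome generator.
#'
#' @param consensus DNA string (ACGT only).
#' @param identity Probability of the consensus base at each position.
#' @param name Motif name.
#' @return A `pwm` object with `n_sites = 0`.
#' @export
pwm_from_consensus <- function(consensus, identity = 0.95, name = consensus) {
  codes <- seq_codes(toupper(consensus))
  if (anyNA(codes)) stop("consensus may only contain A, C, G, T")
  probs <- matrix((1 - identity) / 3, nrow = length(codes), ncol = 4L,
                  dimnames = list(NULL, DNA_BASES))
  probs[cbind(seq_along(codes), codes)] <- identity
  new_pwm(probs, name = name, pseudocount = 0, n_sites = 0L)
}

#' Consensus sequence of a PWM
#'
#' @param pwm A `pwm` object.
#' @return The string of per-position most probable bases (ties broken A<C<G<T).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 1L, which.max)], collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "': width ", x$width, ", built from ", x$n_sites,
      " sites (pseudocount ", x$pseudocount, ")\n", sep = "")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Background base composition
#'
#' A 0-order background model over A, C, G, T used for log-odds scoring and
#' p-value calibration.
#'
#' @param freqs Named or unnamed numeric vector of 4 probabilities in A, C, G,
#'   T order, or `NULL` for a uniform background.
#' @param source Provenance label: one of `"uniform"`, `"genome-estimated"`,
#'   `"user-supplied"`.
#' @return A `background` object.
#' @export
make_background <- function(freqs = NULL,
                            source = if (is.null(freqs)) "uniform" else "user-supplied") {
  if (is.null(freqs)) freqs <- rep(0.25, 4L)
  if (length(freqs) != 4L) stop("background needs 4 frequencies (A, C, G, T)")
  if (!is.null(names(freqs))) freqs <- freqs[DNA_BASES]
  freqs <- as.numeric(freqs)
  if (abs(sum(freqs) - 1) > 1e-9) stop("background frequencies must sum to 1")
  if (any(freqs <= 0)) stop("background frequencies must all be positive")
  structure(list(freqs = setNames(freqs, DNA_BASES), source = source),
            class = "background")
}

#' Estimate a 0-order background from an assembly
#'
#' Pools base counts over all contigs (both strands are implied by scanning,
#' but composition is taken from the forward strand as supplied). One
#' pseudo-observation per base guards against degenerate assemblies.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @return A `background` with `source = "genome-estimated"`.
#' @export
estimate_background <- function(genome) {
  contigs <- as_contig_vector(genome)
  counts <- rep(0, 4L)
  for (s in contigs) {
    codes <- seq_codes(s)
    counts <- counts + tabulate(codes, nbins = 4L)
  }
  make_background((counts + 1) / (sum(counts) + 4), source = "genome-estimated")
}

#' @export
print.background <- function(x, ...) {
  cat("background (", x$source, "): ",
      paste(sprintf("%s=%.4f", DNA_BASES, x$freqs), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Log-odds scoring matrix of a PWM against a background
#'
#' `entry[i, b] = log2(probs[i, b] / background$freqs[b])`; the score of a
#' word is the sum of its per-position entries, in bits.
#'
#' @param pwm A `pwm`.
#' @param background A `background` (default uniform).
#' @return A `width x 4` numeric matrix.
#' @export
log_odds <- function(pwm, background = make_background()) {
  if (any(pwm$probs == 0)) {
    stop("pwm '", pwm$name, "' contains zero probabilities; rebuild it with a ",
         "positive pseudocount before log-odds scoring")
  }
  lo <- log2(sweep(pwm$probs, 2L, background$freqs, "/"))
  colnames(lo) <- DNA_BASES
  lo
}

#' Maximum achievable log-odds score of a PWM
#'
#' @inheritParams log_odds
#' @return The best possible word score, in bits.
#' @export
max_log_odds_score <- function(pwm, background = make_background()) {
  sum(apply(log_odds(pwm, background), 1L, max))
}
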