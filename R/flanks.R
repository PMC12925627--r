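#' Export flanking sequence around retained centromere calls
#'
#' Extracts up to `flank` bp on each side of every retained call (truncated
#' at contig edges), for downstream synteny verification with external
#' homology tools; no homology engine is bundled.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector the
#'   calls were made on.
#' @param annotation A `cen_annotation`.
#' @param flank Flank length in bp on each side (default 10000).
#' @param path Optional FASTA output path.
#' @return A named character vector of flanked regions
#'   (`<contig>:<start>-<end>` names, 0-based half-open), invisibly written
#'   to `path` when given.
#' @export
extract_flanks <- function(genome, annotation, flank = 10000L, path = NULL) {
  stopifnot(inherits(annotation, "cen_annotation"))
  contigs <- as_contig_vector(genome)
  calls <- annotation$retained
  out <- character(nrow(calls))
  nms <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    L <- nchar(contigs[[calls$contig[i]]])
    s <- max(calls$start[i] - flank, 0L)
    e <- min(calls$end[i] + flank, L)
    out[i] <- substring(contigs[[calls$contig[i]]], s + 1L, e)
    nms[i] <- sprintf("%s:%d-%d", calls$contig[i], s, e)
  }
  names(out) <- nms
  if (!is.null(path)) write_fasta(out, path)
  invisible(out)
}
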