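#' Write point-centromere annotations
#'
#' `tsv` mirrors the standard supplementary-table schema: species name,
#' assembly identifier, genome size, contig, centromere number, full
#' centromere sequence, CDEI sequence, CDEIII sequence, CDEII sequence,
#' CDEII length and CDEII AT content (plus `status` when removed calls are
#' kept). `gff3` writes 1-based inclusive coordinates with a `centromere`
#' parent feature and `CDEI`/`CDEII`/`CDEIII` children; `bed` writes 0-based
#' half-open intervals. Coordinate conversions are lossless
#' (GFF3 start = BED start + 1).
#'
#' @param annotation A `cen_annotation` from [annotate_point_centromeres()].
#' @param path Output file path.
#' @param format One of `"tsv"`, `"gff3"`, `"bed"`.
#' @param keep_removed Include calls removed by the filter cascade (TSV gains
#'   a `status` column; GFF3/BED always contain retained calls only).
#' @param species,assembly Label columns for the TSV schema.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path,
                             format = c("tsv", "gff3", "bed"),
                             keep_removed = FALSE,
                             species = "synthetic", assembly = "NA") {
  format <- match.arg(format)
  stopifnot(inherits(annotation, "cen_annotation"))
  calls <- if (keep_removed && format == "tsv") {
    annotation$calls
  } else {
    annotation$retained
  }
  calls <- calls[order(calls$contig, calls$start), , drop = FALSE]

  if (format == "tsv") {
    tab <- data.frame(
      species = species, assembly = assembly,
      genome_size = annotation$genome_size, contig = calls$contig,
      centromere_number = seq_len(nrow(calls)),
      full_sequence = calls$full_seq, cdei_sequence = calls$cdei_seq,
      cdeiii_sequence = calls$cdeiii_seq, cdeii_sequence = calls$cdeii_seq,
      cdeii_length = calls$cdeii_length,
      cdeii_at_content = round(calls$cdeii_at, 2),
      stringsAsFactors = FALSE)
    if (keep_removed) tab$status <- calls$status
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }

  gr <- calls_to_granges(calls)
  if (format == "gff3") {
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    rtracklayer::export(gr[gr$type == "centromere"], path, format = "bed")
  }
  invisible(path)
}

# retained calls -> GRanges with centromere parents and element children;
# internal coordinates are 0-based half-open, GRanges/IRanges are 1-based
# inclusive, hence the +1 on starts only
calls_to_granges <- function(calls) {
  n <- nrow(calls)
  ids <- sprintf("CEN%d", seq_len(n))
  mk <- function(start, end, type, id, parent) {
    GenomicRanges::GRanges(
      seqnames = calls$contig,
      ranges = IRanges::IRanges(start = start + 1L, end = end),
      strand = calls$orientation,
      type = type, ID = id,
      Parent = if (is.null(parent)) IRanges::CharacterList(
        rep(list(character(0)), n)) else IRanges::CharacterList(
          as.list(parent)),
      score = calls$combined_score,
      Name = id)
  }
  parent <- mk(calls$start, calls$end, "centromere", ids, NULL)
  cdei <- mk(calls$cdei_start, calls$cdei_end, "CDEI",
             paste0(ids, "_CDEI"), ids)
  cdeii <- mk(calls$cdeii_start, calls$cdeii_end, "CDEII",
              paste0(ids, "_CDEII"), ids)
  cdeiii <- mk(calls$cdeiii_start, calls$cdeiii_end, "CDEIII",
               paste0(ids, "_CDEIII"), ids)
  keep_ii <- calls$cdeii_end > calls$cdeii_start
  out <- c(parent, cdei, cdeii[keep_ii], cdeiii)
  out[order(as.character(GenomicRanges::seqnames(out)),
            GenomicRanges::start(out))]
}

#' Write core-centromere annotations as TSV
#'
#' Columns mirror the core-centromere supplementary schema: species name,
#' assembly identifier, genome size, contig, centromere number, full
#' sequence (motif plus available downstream), motif sequence, and AT
#' content of the first 100 bp downstream of the motif; the estimated
#' AT-region length and truncation flag are appended.
#'
#' @param annotation A `core_annotation` from [annotate_core_centromeres()].
#' @param path Output file path.
#' @param species,assembly Label columns.
#' @return `path`, invisibly.
#' @export
write_core_annotation <- function(annotation, path, species = "synthetic",
                                  assembly = "NA") {
  stopifnot(inherits(annotation, "core_annotation"))
  calls <- annotation$calls
  calls <- calls[order(calls$contig, calls$start), , drop = FALSE]
  tab <- data.frame(
    species = species, assembly = assembly,
    genome_size = annotation$genome_size, contig = calls$contig,
    centromere_number = seq_len(nrow(calls)),
    full_sequence = paste0(calls$matched_seq, calls$downstream_seq),
    motif_sequence = calls$matched_seq,
    at100_downstream = round(calls$at100_downstream, 2),
    at_region_length = calls$at_region_length,
    truncated = calls$truncated,
    bona_fide = calls$bona_fide,
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
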