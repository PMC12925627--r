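IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", ".")

#' Read a multi-record FASTA file
#'
#' Wrapped and unwrapped records are accepted; lowercase letters are
#' uppercased. Any character outside the IUPAC nucleotide alphabet raises an
#' error naming the offending character and record.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] with record headers as names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  seqs <- toupper(as.character(raw))
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, IUPAC_CHARS)
    if (length(bad)) {
      stop("record '", names(seqs)[i], "' in '", path,
           "' contains non-IUPAC character '", bad[1L], "'")
    }
  }
  Biostrings::DNAStringSet(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read aligned motif sites from a plain text file
#'
#' One site per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Uppercased character vector of sites.
#' @export
read_sites <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no sites found in ", path)
  toupper(lines)
}
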