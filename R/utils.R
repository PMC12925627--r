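#' @importFrom methods is
#' @importFrom stats median runif setNames
#' @importFrom utils head write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# byte -> base code lookup (1=A, 2=C, 3=G, 4=T, NA otherwise); lowercase accepted
.code_tab <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("a")] <- 1L
  tab[utf8ToInt("C")] <- 2L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("g")] <- 3L
  tab[utf8ToInt("T")] <- 4L; tab[utf8ToInt("t")] <- 4L
  tab
})

# encode a DNA string as integer codes; non-ACGT become NA
seq_codes <- function(seq) {
  .code_tab[utf8ToInt(seq)]
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented through [Biostrings::reverseComplement()].
#'
#' @param seq A single DNA string.
#' @return The reverse-complemented string, preserving case as uppercase.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' AT content of a DNA string, in percent
#'
#' Ambiguous (non-ACGT) bases are excluded from both numerator and denominator.
#'
#' @param seq A single DNA string.
#' @return AT percentage in \[0, 100\], or `NA` if no unambiguous base is present.
#' @export
at_percent <- function(seq) {
  codes <- seq_codes(seq)
  n <- sum(!is.na(codes))
  if (n == 0L) return(NA_real_)
  100 * sum(codes == 1L | codes == 4L, na.rm = TRUE) / n
}

gc_percent <- function(seq) {
  codes <- seq_codes(seq)
  n <- sum(!is.na(codes))
  if (n == 0L) return(NA_real_)
  100 * sum(codes == 2L | codes == 3L, na.rm = TRUE) / n
}

# coerce genome input (file path, DNAStringSet, or named character) to a named
# uppercase character vector of contig sequences
as_contig_vector <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- read_fasta(genome)
  }
  if (is(genome, "DNAStringSet") || is(genome, "BStringSet")) {
    genome <- setNames(toupper(as.character(genome)), names(genome))
  } else if (is.character(genome)) {
    genome <- toupper(genome)
    if (is.null(names(genome))) {
      names(genome) <- paste0("contig_", seq_along(genome))
    }
  } else {
    stop("genome must be a FASTA path, a DNAStringSet, or a named character vector")
  }
  genome
}

# run code with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
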