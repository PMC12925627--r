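#' Read motifs from a MEME minimal format file
#'
#' Parses the MEME minimal motif format: a `MEME version` line, an
#' `ALPHABET= ACGT` line, optional strand and background-frequency sections,
#' and one or more `MOTIF` blocks each followed by a
#' `letter-probability matrix:` header and `w` rows of 4 probabilities.
#' Every matrix row must sum to 1 within 1e-3 (values are re-normalized
#' exactly after validation).
#'
#' @param path File path.
#' @return A list of `pwm` objects, in file order; the file's background
#'   frequencies (if present) are attached as attribute `"background"`.
#' @export
read_meme_minimal <- function(path) {
  lines <- trimws(readLines(path))
  if (!any(grepl("^MEME version", lines))) {
    stop("'", path, "' is not MEME minimal format (missing 'MEME version' line)")
  }
  alpha <- grep("^ALPHABET\\s*=", lines, value = TRUE)
  if (!length(alpha)) stop("'", path, "' is missing an ALPHABET line")
  alpha_str <- gsub("\\s", "", sub("^ALPHABET\\s*=", "", alpha[1L]))
  if (toupper(alpha_str) != "ACGT") {
    stop("unsupported alphabet '", alpha_str, "' (only ACGT is supported)")
  }

  background <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    bg_line <- lines[bg_at[1L] + 1L]
    toks <- strsplit(bg_line, "\\s+")[[1L]]
    freqs <- as.numeric(toks[seq(2L, length(toks), by = 2L)])
    names(freqs) <- toupper(toks[seq(1L, length(toks), by = 2L)])
    background <- make_background(freqs, source = "user-supplied")
  }

  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found in ", path)
  pwms <- vector("list", length(motif_at))
  for (m in seq_along(motif_at)) {
    i <- motif_at[m]
    name <- strsplit(lines[i], "\\s+")[[1L]][2L]
    j <- i + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) {
      stop("MOTIF '", name, "' has no letter-probability matrix")
    }
    w <- suppressWarnings(
      as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j])))
    nsites <- suppressWarnings(
      as.integer(sub(".*\\bnsites=\\s*(\\d+).*", "\\1", lines[j])))
    if (is.na(nsites)) nsites <- 0L
    rows <- lines[(j + 1L):length(lines)]
    rows <- rows[nzchar(rows)]
    is_num <- grepl("^[-0-9.eE+ \t]+$", rows)
    run_len <- if (any(!is_num)) which(!is_num)[1L] - 1L else length(rows)
    if (is.na(w)) w <- run_len
    if (run_len < w) {
      stop("MOTIF '", name, "': expected ", w, " matrix rows, found ", run_len)
    }
    mat <- t(vapply(rows[seq_len(w)],
                    function(r) as.numeric(strsplit(r, "\\s+")[[1L]]),
                    numeric(4L)))
    rownames(mat) <- NULL
    sums <- rowSums(mat)
    bad <- which(abs(sums - 1) > 1e-3)
    if (length(bad)) {
      stop("MOTIF '", name, "': matrix row ", bad[1L], " sums to ",
           format(sums[bad[1L]]), ", not 1")
    }
    mat <- mat / sums
    pwms[[m]] <- new_pwm(mat, name = name, pseudocount = 0, n_sites = nsites)
  }
  attr(pwms, "background") <- background
  pwms
}

#' Write motifs to a MEME minimal format file
#'
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param path Output path.
#' @param background A `background` written to the file header (default
#'   uniform).
#' @param digits Decimal places for matrix entries (round-trip stable at the
#'   default 6).
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(pwms, path, background = make_background(),
                               digits = 6L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, background$freqs),
                     collapse = " "), ""), con)
  for (pwm in pwms) {
    writeLines(paste("MOTIF", pwm$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      pwm$width, max(pwm$n_sites, 1L)), con)
    fmt <- paste0("%.", digits, "f")
    for (i in seq_len(pwm$width)) {
      writeLines(paste(sprintf(fmt, pwm$probs[i, ]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
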