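# shared in-code fixtures: small PWMs, backgrounds, and sequence builders

uniform_bg <- make_background()

yeast_bg <- make_background(c(0.31, 0.19, 0.19, 0.31), source = "user-supplied")

cdei_pwm <- pwm_from_consensus(CDEI_CONSENSUS, identity = 0.95, name = "CDEI")
cdeiii_pwm <- pwm_from_consensus(CDEIII_CONSENSUS, identity = 0.95,
                                 name = "CDEIII")
mucor_pwm <- pwm_from_consensus(MUCOR_MOTIF_CONSENSUS, identity = 0.95,
                                name = "core41")

new_pwm_for_test <- function(m, name = "test") {
  cenevo:::new_pwm(m, name = name)
}

# independent oracle: score one word directly off the log-odds matrix
score_word <- function(word, lo) {
  codes <- match(strsplit(word, "", fixed = TRUE)[[1L]],
                 c("A", "C", "G", "T"))
  sum(lo[cbind(seq_along(codes), codes)])
}

# independent oracle: naive per-window scan of one strand, real scores
naive_scan_strand <- function(seq, pwm, bg, p_threshold, table) {
  lo <- log_odds(pwm, bg)
  w <- pwm$width
  out <- list()
  for (i in seq_len(nchar(seq) - w + 1L)) {
    word <- substring(seq, i, i + w - 1L)
    if (grepl("[^ACGT]", word)) next
    # p-value through the same discretization contract as the scanner
    k <- sum(table$int_mat[cbind(seq_len(w),
                                 match(strsplit(word, "")[[1L]],
                                       c("A", "C", "G", "T")))])
    p <- table$tail[k + 1L]
    if (p <= p_threshold) {
      out[[length(out) + 1L]] <- data.frame(
        start = i - 1L, score = score_word(word, lo), p_value = p,
        matched_seq = word, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), score = numeric(),
                      p_value = numeric(), matched_seq = character()))
  }
  do.call(rbind, out)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a hand-built candidate-call row for cascade tests
make_call <- function(contig = "c1", start = 1000L, cdeii_length = 85L,
                      cdeii_at = 95, combined = 2.8, full_seq = NULL,
                      orientation = "+") {
  end <- start + 8L + cdeii_length + 26L
  if (is.null(full_seq)) {
    full_seq <- paste0("CDEI", contig, start, cdeii_length, cdeii_at)
  }
  data.frame(contig = contig, start = start, end = end,
             orientation = orientation, full_seq = full_seq,
             cdei_seq = "GTCACGTG", cdeii_seq = "x", cdeiii_seq = "y",
             cdei_start = start, cdei_end = start + 8L,
             cdeii_start = start + 8L, cdeii_end = end - 26L,
             cdeiii_start = end - 26L, cdeiii_end = end,
             cdeii_length = cdeii_length, cdeii_at = cdeii_at,
             score_cdei = 10, score_cdeiii = 40,
             combined_score = combined, stringsAsFactors = FALSE)
}
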