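#' Default motif consensus strings
#'
#' Synthetic, field-realistic defaults used by the generator and the
#' pipeline examples: an 8-bp CDEI-like consensus containing the Cbf1-bound
#' E-box CACGTG, a 26-bp CDEIII-like consensus containing the conserved CCGAA
#' core, and a 41-bp mixed-composition core-centromere motif. These are
#' package-defined stand-ins, not sequences taken from any particular genome.
#'
#' @name default_motifs
#' @export
CDEI_CONSENSUS <- "GTCACGTG"

#' @rdname default_motifs
#' @export
CDEIII_CONSENSUS <- "TGTATTTGATTTCCGAAAGTTAAAAC"

#' @rdname default_motifs
#' @export
MUCOR_MOTIF_CONSENSUS <- "GACTTAGCACGTTACCGGATAACTGCATTAGGCATCAACGT"

random_dna <- function(n, gc = 0.38) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_at_seq <- function(n, at = 0.95) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

# per-position substitution to a uniformly chosen OTHER base
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# sample a CDEII length from the class mixture: named numeric vector of
# weights, names = lengths in bp
sample_class <- function(classes) {
  lens <- as.integer(names(classes))
  if (abs(sum(classes) - 1) > 1e-9) stop("class weights must sum to 1")
  lens[sample.int(length(lens), 1L, prob = classes)]
}

#' Specification for a synthetic point-centromere genome
#'
#' Defaults emulate a yeast-like assembly: 16 chromosomes, i.i.d. background
#' at 38% GC, one planted centromere per chromosome built as
#' CDEI + AT-rich CDEII + CDEIII with 5% per-position motif noise and a 95%
#' AT CDEII, plus CDEIII-only decoys and full-structure decoys with an
#' AT-poor (50%) CDEII that the filter cascade must reject.
#'
#' @param n_chromosomes,chrom_length Assembly shape (total default 16 x
#'   750 kb = 12 Mb).
#' @param gc Background GC fraction.
#' @param cdei_consensus,cdeiii_consensus Planted motif consensus strings.
#' @param motif_sub_rate Per-position substitution rate applied to each
#'   planted motif copy.
#' @param cdeii_classes Named weight vector of CDEII length classes, e.g.
#'   `c("50" = 0.5, "61" = 0.5)` for a genome mid-transition between two
#'   centromere types.
#' @param cdeii_at AT fraction of planted CDEII sequence.
#' @param n_decoy_cdeiii Number of CDEIII-only decoy sites.
#' @param n_decoy_lowat Number of full-structure decoys with AT-poor CDEII.
#' @param decoy_at AT fraction of decoy CDEII sequence.
#' @param seed RNG seed.
#' @return A `plant_spec` list.
#' @export
point_genome_spec <- function(n_chromosomes = 16L, chrom_length = 750000L,
                              gc = 0.38,
                              cdei_consensus = CDEI_CONSENSUS,
                              cdeiii_consensus = CDEIII_CONSENSUS,
                              motif_sub_rate = 0.05,
                              cdeii_classes = c("85" = 1),
                              cdeii_at = 0.95,
                              n_decoy_cdeiii = 20L, n_decoy_lowat = 20L,
                              decoy_at = 0.50, seed = 20260101L) {
  stopifnot(n_chromosomes >= 1L, chrom_length >= 2000L,
            abs(sum(cdeii_classes) - 1) < 1e-9)
  structure(as.list(environment()), class = "plant_spec")
}

#' Generate a synthetic genome with planted point centromeres
#'
#' Each chromosome carries exactly one planted centromere at a uniformly
#' chosen interior position and strand; decoys are placed at non-overlapping
#' random positions across chromosomes. A truth table of planted coordinates
#' (0-based half-open, forward strand), strands, classes and realized CDEII
#' length/AT accompanies the sequences.
#'
#' @param spec A [point_genome_spec()].
#' @return List with `genome` (named character vector of contigs) and
#'   `truth` (data frame: contig, start, end, strand, type, cdeii_length,
#'   cdeii_at).
#' @export
make_point_centromere_genome <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    margin <- 1000L
    max_len <- max(as.integer(names(spec$cdeii_classes))) +
      nchar(spec$cdei_consensus) + nchar(spec$cdeiii_consensus)
    if (spec$chrom_length < 2L * margin + 2L * max_len) {
      stop("chrom_length too short for window margins")
    }

    # 1) decide every locus (sequence, strand, chromosome) up front
    loci <- list()
    add_locus <- function(ci, type) {
      if (type == "decoy_cdeiii") {
        site <- mutate_seq(spec$cdeiii_consensus, spec$motif_sub_rate)
        len <- NA_integer_; at <- NA_real_
      } else {
        len <- sample_class(spec$cdeii_classes)
        at_frac <- if (type == "centromere") spec$cdeii_at else spec$decoy_at
        cdeii <- random_at_seq(len, at_frac)
        site <- paste0(mutate_seq(spec$cdei_consensus, spec$motif_sub_rate),
                       cdeii,
                       mutate_seq(spec$cdeiii_consensus, spec$motif_sub_rate))
        at <- at_percent(cdeii)
      }
      strand <- sample(c("+", "-"), 1L)
      loci[[length(loci) + 1L]] <<- list(
        ci = ci, type = type, seq = site, strand = strand,
        cdeii_length = len, cdeii_at = at)
    }
    for (ci in seq_len(spec$n_chromosomes)) add_locus(ci, "centromere")
    for (i in seq_len(spec$n_decoy_cdeiii)) {
      add_locus(sample.int(spec$n_chromosomes, 1L), "decoy_cdeiii")
    }
    for (i in seq_len(spec$n_decoy_lowat)) {
      add_locus(sample.int(spec$n_chromosomes, 1L), "decoy_lowat")
    }

    # 2) place loci per chromosome at non-overlapping final coordinates
    #    (>= 300 bp apart, >= margin from each edge), then assemble the
    #    chromosome from background stretches between them
    genome <- character(spec$n_chromosomes)
    names(genome) <- sprintf("chr%02d", seq_len(spec$n_chromosomes))
    truth <- list()
    for (ci in seq_len(spec$n_chromosomes)) {
      mine <- Filter(function(l) l$ci == ci, loci)
      lens <- vapply(mine, function(l) nchar(l$seq), integer(1))
      repeat {
        s <- sort(sample.int(spec$chrom_length - 2L * margin - max(lens),
                             length(mine), replace = FALSE)) + margin
        e <- s + lens
        if (length(s) < 2L || all(s[-1L] - e[-length(e)] >= 300L)) break
      }
      pieces <- character(2L * length(mine) + 1L)
      prev_end <- 0L
      for (j in seq_along(mine)) {
        pieces[2L * j - 1L] <- random_dna(s[j] - prev_end, spec$gc)
        ins <- if (mine[[j]]$strand == "+") mine[[j]]$seq else
          revcomp(mine[[j]]$seq)
        pieces[2L * j] <- ins
        prev_end <- e[j]
        truth[[length(truth) + 1L]] <- data.frame(
          contig = names(genome)[ci], start = s[j], end = e[j],
          strand = mine[[j]]$strand, type = mine[[j]]$type,
          cdeii_length = mine[[j]]$cdeii_length,
          cdeii_at = mine[[j]]$cdeii_at, stringsAsFactors = FALSE)
      }
      pieces[length(pieces)] <- random_dna(spec$chrom_length - prev_end,
                                           spec$gc)
      genome[[ci]] <- paste(pieces, collapse = "")
      stopifnot(nchar(genome[[ci]]) == spec$chrom_length)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(genome = genome, truth = truth)
  })
}

#' Specification for a synthetic core-centromere genome
#'
#' @param n_loci Number of core-centromere loci (one per contig).
#' @param contig_length Contig length in bp.
#' @param gc Background GC fraction.
#' @param motif_consensus Planted motif (41 bp default).
#' @param motif_sub_rate Per-position substitution rate on planted motifs.
#' @param at_lengths Named weight vector of AT-run length classes, e.g.
#'   `c("400" = 1)` or `c("220" = 0.5, "400" = 0.5)`.
#' @param at_fraction AT fraction of the planted AT run.
#' @param n_truncated Number of loci planted so close to the contig 3' end
#'   that the AT run (and the 750-bp downstream stretch) is cut short.
#' @param truncate_at Remaining downstream bp for truncated loci.
#' @param seed RNG seed.
#' @return A `mucor_spec` list.
#' @export
mucor_genome_spec <- function(n_loci = 10L, contig_length = 50000L,
                              gc = 0.38,
                              motif_consensus = MUCOR_MOTIF_CONSENSUS,
                              motif_sub_rate = 0.05,
                              at_lengths = c("400" = 1),
                              at_fraction = 0.92,
                              n_truncated = 0L, truncate_at = 600L,
                              seed = 20260101L) {
  stopifnot(n_loci >= 1L, abs(sum(at_lengths) - 1) < 1e-9,
            n_truncated <= n_loci)
  structure(as.list(environment()), class = "mucor_spec")
}

#' Generate a synthetic genome with planted core centromeres
#'
#' Plants one motif + AT-run locus per contig at a random interior position
#' and strand. Optionally some loci are placed so that the contig ends inside
#' the AT run, emulating the short centromere-bearing contigs of fragmented
#' assemblies.
#'
#' @param spec A [mucor_genome_spec()].
#' @return List with `genome` (named character vector) and `truth`
#'   (contig, motif_start, motif_end, strand, at_length planted,
#'   truncated flag, downstream_available).
#' @export
make_mucor_genome <- function(spec) {
  stopifnot(inherits(spec, "mucor_spec"))
  with_seed(spec$seed, {
    w <- nchar(spec$motif_consensus)
    genome <- character(spec$n_loci)
    names(genome) <- sprintf("scaffold%02d", seq_len(spec$n_loci))
    truth <- vector("list", spec$n_loci)
    for (i in seq_len(spec$n_loci)) {
      at_len <- sample_class(spec$at_lengths)
      motif <- mutate_seq(spec$motif_consensus, spec$motif_sub_rate)
      at_run <- random_at_seq(at_len, spec$at_fraction)
      locus <- paste0(motif, at_run)
      truncated <- i <= spec$n_truncated
      if (truncated) {
        avail <- min(spec$truncate_at, at_len)
        left <- random_dna(spec$contig_length - w - avail, spec$gc)
        seq_fwd <- paste0(left, motif, substring(at_run, 1L, avail))
        motif_start <- nchar(left)
        downstream_avail <- avail
      } else {
        pos <- sample.int(spec$contig_length - nchar(locus) - 2000L, 1L) + 1000L
        left <- random_dna(pos, spec$gc)
        right <- random_dna(spec$contig_length - pos - nchar(locus), spec$gc)
        seq_fwd <- paste0(left, locus, right)
        motif_start <- pos
        downstream_avail <- nchar(seq_fwd) - (motif_start + w)
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "+") {
        genome[[i]] <- seq_fwd
        ms <- motif_start
      } else {
        genome[[i]] <- revcomp(seq_fwd)
        ms <- nchar(seq_fwd) - (motif_start + w)
      }
      truth[[i]] <- data.frame(
        contig = names(genome)[i], motif_start = ms, motif_end = ms + w,
        strand = strand, at_length = at_len, truncated = truncated,
        downstream_available = downstream_avail, stringsAsFactors = FALSE)
    }
    list(genome = genome, truth = do.call(rbind, truth))
  })
}

#' Generate a synthetic strain population with CDEII-length variants
#'
#' Emulates intraspecific centromere variation: each strain genome carries 16
#' point centromeres of a base CDEII length class; a `variant_fraction` of
#' strains carry 1-2 centromeres whose CDEII was lengthened or shortened by
#' `variant_delta_bp` through a microhomology-mediated mechanism (an inserted
#' stretch is an exact copy of the immediately preceding stretch; a
#' shortening deletes a stretch).
#'
#' @param n_strains Number of strains.
#' @param variant_fraction Fraction of strains carrying variants, in \[0, 1\].
#' @param variant_delta_bp Length change per variant centromere (default 10).
#' @param base_spec A [point_genome_spec()] template for each strain (made
#'   small by default: 16 x 6-kb contigs, no decoys).
#' @param seed RNG seed.
#' @return List with `genomes` (list of named character vectors, one per
#'   strain) and `truth` (strain, is_variant, n_variant_centromeres,
#'   variant_lengths as comma string).
#' @export
make_strain_population <- function(n_strains, variant_fraction,
                                   variant_delta_bp = 10L,
                                   base_spec = point_genome_spec(
                                     chrom_length = 6000L,
                                     n_decoy_cdeiii = 0L, n_decoy_lowat = 0L),
                                   seed = 20260101L) {
  stopifnot(variant_fraction >= 0, variant_fraction <= 1)
  with_seed(seed, {
    n_var <- round(variant_fraction * n_strains)
    is_variant <- seq_len(n_strains) %in% sample.int(n_strains, n_var)
    base_len <- as.integer(names(base_spec$cdeii_classes))[
      which.max(base_spec$cdeii_classes)]
    genomes <- vector("list", n_strains)
    truth <- vector("list", n_strains)
    for (s in seq_len(n_strains)) {
      sp <- base_spec
      sp$seed <- NULL # draw from the current stream
      sp <- structure(sp, class = "plant_spec")
      g <- make_point_centromere_genome(sp)
      variant_lengths <- integer(0)
      if (is_variant[s]) {
        k <- sample(1:2, 1L)
        rows <- sample(which(g$truth$type == "centromere"), k)
        for (ri in rows) {
          ctg <- g$truth$contig[ri]
          res <- apply_microhomology_variant(
            g$genome[[ctg]], g$truth, ri, variant_delta_bp)
          g$genome[[ctg]] <- res$seq
          variant_lengths <- c(variant_lengths, res$new_length)
        }
      }
      genomes[[s]] <- g$genome
      truth[[s]] <- data.frame(
        strain = sprintf("strain%03d", s), is_variant = is_variant[s],
        n_variant_centromeres = length(variant_lengths),
        variant_lengths = paste(variant_lengths, collapse = ","),
        stringsAsFactors = FALSE)
    }
    names(genomes) <- sprintf("strain%03d", seq_len(n_strains))
    list(genomes = genomes, truth = do.call(rbind, truth))
  })
}

# lengthen (duplicate an internal stretch in place: ...XY -> ...X X Y...) or
# shorten (delete a stretch) the CDEII of the centromere in truth row ri
apply_microhomology_variant <- function(chrom_seq, truth, ri, delta) {
  cen_start <- truth$start[ri]
  cen_end <- truth$end[ri]
  strand <- truth$strand[ri]
  cen <- substring(chrom_seq, cen_start + 1L, cen_end)
  if (strand == "-") cen <- revcomp(cen)
  w1 <- 8L # CDEI width of the planted structure
  cdeii_len <- truth$cdeii_length[ri]
  lengthen <- runif(1L) < 0.5 || cdeii_len <= delta + 2L
  ii_off <- w1 # CDEII begins after CDEI
  if (lengthen) {
    at <- sample.int(cdeii_len - delta, 1L) + ii_off # stretch [at+1, at+delta]
    stretch <- substring(cen, at + 1L, at + delta)
    new_cen <- paste0(substring(cen, 1L, at + delta), stretch,
                      substring(cen, at + delta + 1L, nchar(cen)))
    new_length <- cdeii_len + delta
  } else {
    at <- sample.int(cdeii_len - delta, 1L) + ii_off
    new_cen <- paste0(substring(cen, 1L, at),
                      substring(cen, at + delta + 1L, nchar(cen)))
    new_length <- cdeii_len - delta
  }
  if (strand == "-") new_cen <- revcomp(new_cen)
  seq <- paste0(substring(chrom_seq, 1L, cen_start), new_cen,
                substring(chrom_seq, cen_end + 1L, nchar(chrom_seq)))
  list(seq = seq, new_length = new_length)
}

#' Classify strains by variant CDEII lengths
#'
#' A strain is flagged as a variant carrier when any of its retained
#' centromere calls has a CDEII length below `lower` or above `upper` bp
#' (the regular class being `lower`..`upper`).
#'
#' @param annotations Named list of `cen_annotation` objects (or retained-call
#'   data frames), one per strain.
#' @param lower,upper Regular CDEII length band in bp (defaults 80 and 90).
#' @return Data frame: strain, n_variant_centromeres, is_variant.
#' @export
classify_strain_variants <- function(annotations, lower = 80, upper = 90) {
  rows <- lapply(names(annotations), function(nm) {
    a <- annotations[[nm]]
    calls <- if (inherits(a, "cen_annotation")) a$retained else a
    nv <- sum(calls$cdeii_length < lower | calls$cdeii_length > upper)
    data.frame(strain = nm, n_variant_centromeres = nv,
               is_variant = nv > 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
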