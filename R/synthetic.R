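# Synthetic training/test corpus generator with recorded ground truth.
#
# Genes are alternating introns and internal exons on a uniform ACGT
# background. Splice sites are emitted from consensus tables whose per-base
# consensus probability rises with the site's intended strength class, exon
# lengths follow a Beta law whose shape depends on the flanking strengths
# (stronger sites -> shorter exons), a configurable fraction of donors is
# non-canonical GC, and an intronic enhancer motif is planted downstream of
# true donors at a higher rate than near decoy donors. Generation is a pure
# function of (spec, seed).

DONOR_GT_CONSENSUS <- "CAGGTAAGT"
DONOR_GC_CONSENSUS <- "CAGGCAAGT"
# 18 intronic nt (pyrimidine tract + AG) then 3 exonic nt.
ACCEPTOR_CONSENSUS <- "TTTTTTTTCCTTTTTCAGGTG"

#' Specification of a synthetic splicing corpus
#'
#' @param seed RNG seed; generation is a pure function of the spec.
#' @param n_genes number of genes (default 200).
#' @param exons_per_gene internal exons per gene (default 2).
#' @param gc_donor_fraction probability a true donor is non-canonical GC
#'   (default 0.01).
#' @param intron_len_range uniform intron length range in nt (default
#'   800..1200, long enough to carry pseudoexon flanks).
#' @param strength_range intended site strength classes to sample from
#'   (default 1:5; strength 5 emits the exact consensus).
#' @param exon_len_alpha Beta alpha of the exon length law (default 2.5).
#' @param exon_len_beta_base,exon_len_beta_slope the Beta beta parameter is
#'   base + slope * (s3 + s5), so stronger flanking sites give shorter
#'   exons (defaults 1 and 0.7).
#' @param max_len exon length scale in nt (default 400).
#' @param min_exon_len shortest planted exon (default 30 nt).
#' @param ise_motif intronic enhancer motif planted downstream of donors
#'   (default GGGGTGGG).
#' @param ise_rate_true,ise_rate_decoy planting probabilities near true and
#'   decoy donors (defaults 0.10 and 0.01).
#' @param ise_offset_range intronic start-offset range for planting
#'   (default 15..60 nt after the donor).
#' @param decoy_plants_per_intron decoy donor/acceptor signals planted into
#'   each intron (default 2).
#' @param decoy_plant_strength consensus class the planted decoys are
#'   emitted from (default 1, the weakest).
#' @param flank element-context flank length in nt (default 205).
#' @return object of class \code{corpus_spec}.
#' @export
corpus_spec <- function(seed = 1L, n_genes = 200L, exons_per_gene = 2L,
                        gc_donor_fraction = 0.01,
                        intron_len_range = c(800L, 1200L),
                        strength_range = 1:5,
                        exon_len_alpha = 2.5, exon_len_beta_base = 1,
                        exon_len_beta_slope = 0.7,
                        max_len = 400L, min_exon_len = 30L,
                        ise_motif = "GGGGTGGG",
                        ise_rate_true = 0.10, ise_rate_decoy = 0.01,
                        ise_offset_range = c(15L, 60L),
                        decoy_plants_per_intron = 2L,
                        decoy_plant_strength = 1L,
                        flank = 205L) {
  stopifnot(gc_donor_fraction >= 0, gc_donor_fraction <= 1,
            ise_rate_true >= 0, ise_rate_true <= 1,
            ise_rate_decoy >= 0, ise_rate_decoy <= 1,
            min_exon_len >= 6L, max_len > min_exon_len)
  if (diff(range(intron_len_range)) < 0 ||
      min(intron_len_range) < 2L * flank) {
    stop("introns must be at least twice the flank length", call. = FALSE)
  }
  structure(as.list(environment()), class = "corpus_spec")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample() treats a scalar first argument as 1:x; guard against that.
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Per-base consensus probability of a strength class.
strength_consensus_prob <- function(s) 0.5 + 0.1 * s

# Emit an oligo from a consensus string: each base is the consensus base
# with probability p, otherwise uniform over the other three; positions in
# `fixed` always emit the consensus base (the splice anchor).
emit_oligo <- function(consensus, p, fixed = integer(0)) {
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  out <- vapply(seq_along(cons), function(i) {
    if (i %in% fixed || stats::runif(1) < p) cons[i]
    else sample(setdiff(c("A", "C", "G", "T"), cons[i]), 1)
  }, character(1))
  paste(out, collapse = "")
}

emit_donor <- function(s, kind) {
  cons <- if (kind == "donor_GC") DONOR_GC_CONSENSUS else DONOR_GT_CONSENSUS
  emit_oligo(cons, strength_consensus_prob(s), fixed = c(4L, 5L))
}

emit_acceptor <- function(s) {
  emit_oligo(ACCEPTOR_CONSENSUS, strength_consensus_prob(s),
             fixed = c(17L, 18L))
}

#' Generate a synthetic splicing corpus
#'
#' @param spec a \code{corpus_spec}.
#' @return object of class \code{synthetic_corpus}: \code{spec},
#'   \code{genes} (named character vector), \code{truth} (one row per
#'   planted exon: gene, acceptor_pos, donor_pos, length, s3, s5,
#'   donor_kind, has_ise), \code{true_donor_oligos} (+ kinds),
#'   \code{true_acceptor_oligos}, \code{decoy_donor_oligos},
#'   \code{decoy_acceptor_oligos}, \code{true_donor_flanks},
#'   \code{decoy_donor_flanks} (element contexts, \code{flank} nt of intron
#'   downstream of the signal), and \code{introns}.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  genes <- character(spec$n_genes)
  names(genes) <- sprintf("gene%03d", seq_len(spec$n_genes))
  truth <- list(); introns <- character(0)
  true_don <- character(0); true_don_kind <- character(0)
  true_acc <- character(0)
  decoy_don <- character(0); decoy_acc <- character(0)
  true_flanks <- character(0); decoy_flanks <- character(0)

  intron_piece <- function() {
    len <- sample1(seq(spec$intron_len_range[1], spec$intron_len_range[2]))
    seq <- rand_dna(len)
    # planted decoy signals (weakest class), away from the intron ends
    plants <- list(don = character(0), don_at = integer(0))
    if (spec$decoy_plants_per_intron > 0L && len > 2L * spec$flank + 80L) {
      at <- sort(sample(seq(spec$flank, len - spec$flank - 30L),
                        spec$decoy_plants_per_intron))
      for (a in at) {
        if (stats::runif(1) < 0.5) {
          o <- emit_donor(spec$decoy_plant_strength, "donor_GT")
          substr(seq, a, a + 8L) <- o
          plants$don <- c(plants$don, o)
          plants$don_at <- c(plants$don_at, a)
        } else {
          o <- emit_acceptor(spec$decoy_plant_strength)
          substr(seq, a, a + 20L) <- o
          decoy_acc <<- c(decoy_acc, o)
        }
      }
      # enhancer planting near decoy donors (low rate)
      for (a in plants$don_at) {
        if (stats::runif(1) < spec$ise_rate_decoy) {
          off <- sample1(seq(spec$ise_offset_range[1],
                             spec$ise_offset_range[2]))
          # offset is relative to the decoy intron start (position a + 3)
          st <- a + 3L + off
          if (st + nchar(spec$ise_motif) - 1L <= len) {
            substr(seq, st, st + nchar(spec$ise_motif) - 1L) <- spec$ise_motif
          }
        }
      }
    }
    list(seq = seq, plants = plants)
  }

  for (g in seq_len(spec$n_genes)) {
    parts <- character(0)
    pos <- 0L  # 0-based length so far
    first <- intron_piece()
    decoy_don <- c(decoy_don, first$plants$don)
    for (a in first$plants$don_at) {
      fl <- substr(first$seq, a + 3L, a + 2L + spec$flank)
      if (nchar(fl) == spec$flank) decoy_flanks <- c(decoy_flanks, fl)
    }
    introns <- c(introns, first$seq)
    parts <- c(parts, first$seq); pos <- pos + nchar(first$seq)
    for (e in seq_len(spec$exons_per_gene)) {
      s3 <- sample1(spec$strength_range)
      s5 <- sample1(spec$strength_range)
      kind <- if (stats::runif(1) < spec$gc_donor_fraction) "donor_GC"
      else "donor_GT"
      beta_par <- spec$exon_len_beta_base +
        spec$exon_len_beta_slope * (s3 + s5)
      len <- round(spec$max_len *
                     stats::rbeta(1, spec$exon_len_alpha, beta_par))
      len <- min(max(len, spec$min_exon_len), spec$max_len - 1L)
      acc <- emit_acceptor(s3)
      don <- emit_donor(s5, kind)
      body <- rand_dna(len)
      # acceptor oligo: last 18 nt of the preceding intron + first 3 of exon
      prev <- parts[length(parts)]
      substr(prev, nchar(prev) - 17L, nchar(prev)) <- substr(acc, 1L, 18L)
      parts[length(parts)] <- prev
      substr(body, 1L, 3L) <- substr(acc, 19L, 21L)
      # donor oligo: last 3 nt of exon + first 6 of the following intron
      substr(body, len - 2L, len) <- substr(don, 1L, 3L)
      nxt <- intron_piece()
      decoy_don <- c(decoy_don, nxt$plants$don)
      for (a in nxt$plants$don_at) {
        fl <- substr(nxt$seq, a + 3L, a + 2L + spec$flank)
        if (nchar(fl) == spec$flank) decoy_flanks <- c(decoy_flanks, fl)
      }
      introns <- c(introns, nxt$seq)
      nxt_seq <- nxt$seq
      substr(nxt_seq, 1L, 6L) <- substr(don, 4L, 9L)
      has_ise <- stats::runif(1) < spec$ise_rate_true
      if (has_ise) {
        off <- sample1(seq(spec$ise_offset_range[1],
                           spec$ise_offset_range[2]))
        substr(nxt_seq, off + 1L, off + nchar(spec$ise_motif)) <-
          spec$ise_motif
      }
      acceptor_pos <- pos  # 0-based first exonic nt
      donor_pos <- pos + len  # 0-based first intronic nt
      parts <- c(parts, body, nxt_seq)
      pos <- pos + len + nchar(nxt_seq)
      true_acc <- c(true_acc, acc)
      true_don <- c(true_don, don); true_don_kind <- c(true_don_kind, kind)
      true_flanks <- c(true_flanks, substr(nxt_seq, 1L, spec$flank))
      truth[[length(truth) + 1L]] <- data.frame(
        gene = names(genes)[g], acceptor_pos = acceptor_pos,
        donor_pos = donor_pos, length = len, s3 = s3, s5 = s5,
        donor_kind = kind, has_ise = has_ise, stringsAsFactors = FALSE)
    }
    genes[g] <- paste(parts, collapse = "")
  }
  structure(list(spec = spec, genes = genes,
                 truth = do.call(rbind, truth),
                 true_donor_oligos = true_don,
                 true_donor_kinds = true_don_kind,
                 true_acceptor_oligos = true_acc,
                 decoy_donor_oligos = decoy_don,
                 decoy_acceptor_oligos = decoy_acc,
                 true_donor_flanks = true_flanks,
                 decoy_donor_flanks = decoy_flanks,
                 introns = introns),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("synthetic corpus: %d genes, %d planted exons (%d GC donors)\n",
              length(x$genes), nrow(x$truth),
              sum(x$truth$donor_kind == "donor_GC")))
  invisible(x)
}

#' Harvest decoy splice-like oligos from corpus introns
#'
#' Samples intronic positions carrying the sensor's anchor dinucleotide
#' (away from planted signals) and extracts their windows, giving the decoy
#' count tables their raw material.
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param kind sensor kind.
#' @param max_per_intron cap on sampled decoys per intron (default 25).
#' @return character vector of decoy oligos.
#' @export
harvest_decoy_oligos <- function(corpus, kind, max_per_intron = 25L) {
  win <- default_window(kind)
  up <- win[["upstream_nt"]]; k <- sum(win)
  anc <- sensor_anchor(kind)
  out <- lapply(corpus$introns, function(intr) {
    n <- nchar(intr)
    if (n < k + 2L) return(character(0))
    m <- gregexpr(anc, intr, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(character(0))
    if (kind == "acceptor") {
      start1 <- as.integer(m) + 2L - up  # oligo start, AG ends the intron part
    } else {
      start1 <- as.integer(m) - up       # GT/GC opens the intron part
    }
    start1 <- start1[start1 >= 1L & start1 + k - 1L <= n]
    if (length(start1) > max_per_intron) {
      start1 <- sort(sample(start1, max_per_intron))
    }
    substring(intr, start1, start1 + k - 1L)
  })
  unlist(out)
}

#' Generate aberrant-splicing variant cases with known truth
#'
#' Builds dedicated single-exon case genes (deterministic consensus sites)
#' and a disruptive variant per case, cycling through three scenarios:
#' \describe{
#'   \item{disrupt_gc_donor_delC}{the annotated exon ends in a strong GC
#'     donor carrying a planted cryptic canonical donor a few tens of nt
#'     upstream; deleting the C at intron position +2 abolishes the GC
#'     donor and activates the cryptic donor (case kind
#'     \code{cryptic_SS}).}
#'   \item{disrupt_gt_donor_snv}{as above with a GT donor killed by the
#'     +2 T>A substitution (\code{cryptic_SS}).}
#'   \item{create_cryptic_exon}{a consensus acceptor and an anchor-broken
#'     donor lie in the downstream intron; the +2 A>T substitution restores
#'     the donor and a cryptic exon appears (\code{cryptic_exon}).}
#' }
#'
#' Case geometry (exon length, cryptic-donor offset) is drawn per case so
#' that boundary truths differ between cases.
#'
#' @param n_cases number of cases.
#' @param seed RNG seed.
#' @param intron_len flank intron length (default 400 nt).
#' @param exon_len_range annotated exon length range (default 100..160 nt,
#'   sampled in steps of 4).
#' @param cryptic_offset_range range of the planted cryptic donor's
#'   distance upstream of the annotated donor (default 28..48 nt).
#' @return list of \code{aberrant_case} objects.
#' @export
generate_variant_cases <- function(n_cases, seed = 1L, intron_len = 400L,
                                   exon_len_range = c(100L, 160L),
                                   cryptic_offset_range = c(28L, 48L)) {
  set.seed(seed)
  kinds <- rep(c("disrupt_gc_donor_delC", "disrupt_gt_donor_snv",
                 "create_cryptic_exon"), length.out = n_cases)
  lapply(seq_len(max(n_cases, 0L)), function(i) {
    scenario <- kinds[i]
    exon_len <- sample1(seq(exon_len_range[1], exon_len_range[2], by = 4L))
    cryptic_upstream_offset <- sample1(seq(cryptic_offset_range[1],
                                           cryptic_offset_range[2], by = 4L))
    i1 <- rand_dna(intron_len); i2 <- rand_dna(intron_len)
    body <- rand_dna(exon_len)
    acc <- ACCEPTOR_CONSENSUS
    donor_kind <- if (scenario == "disrupt_gc_donor_delC") "donor_GC"
    else "donor_GT"
    don <- if (donor_kind == "donor_GC") DONOR_GC_CONSENSUS
    else DONOR_GT_CONSENSUS
    substr(i1, intron_len - 17L, intron_len) <- substr(acc, 1L, 18L)
    substr(body, 1L, 3L) <- substr(acc, 19L, 21L)
    substr(body, exon_len - 2L, exon_len) <- substr(don, 1L, 3L)
    substr(i2, 1L, 6L) <- substr(don, 4L, 9L)
    acceptor_pos <- intron_len              # 0-based
    donor_pos <- intron_len + exon_len
    cryptic_pos <- donor_pos - cryptic_upstream_offset
    # cryptic canonical donor fully inside the exon body
    substr(body, cryptic_pos - intron_len - 2L, cryptic_pos - intron_len + 6L) <-
      DONOR_GT_CONSENSUS
    seq <- paste0(i1, body, i2)
    annotation <- data.frame(start = acceptor_pos + 1L, end = donor_pos)
    if (scenario == "create_cryptic_exon") {
      # consensus acceptor + broken donor deep in the downstream intron
      ce_acc_at <- donor_pos + 100L + 4L * sample1(0:8)  # 0-based first exonic nt
      ce_don_at <- ce_acc_at + 60L + 4L * sample1(0:6)   # 0-based first intronic nt
      broken <- DONOR_GT_CONSENSUS
      substr(broken, 5L, 5L) <- "A"        # GT -> GA, anchor broken
      substr(seq, ce_acc_at - 17L, ce_acc_at + 3L) <- acc
      substr(seq, ce_don_at - 2L, ce_don_at + 6L) <- broken
      variant <- variant_spec(ce_don_at + 2L, "A", "T", kind = "SNV",
                              id = sprintf("case%03d_%s", i, scenario))
      aberrant <- data.frame(position = c(ce_acc_at, ce_don_at),
                             side = c("acceptor", "donor"))
      case_kind <- "cryptic_exon"
    } else {
      if (scenario == "disrupt_gc_donor_delC") {
        variant <- variant_spec(donor_pos + 2L, "C", "", kind = "deletion",
                                id = sprintf("case%03d_%s", i, scenario))
      } else {
        variant <- variant_spec(donor_pos + 2L, "T", "A", kind = "SNV",
                                id = sprintf("case%03d_%s", i, scenario))
      }
      aberrant <- data.frame(position = c(acceptor_pos, cryptic_pos),
                             side = c("acceptor", "donor"))
      case_kind <- "cryptic_SS"
    }
    aberrant_case(
      seq, variant, annotation,
      original_boundaries = data.frame(
        position = c(acceptor_pos, donor_pos),
        side = c("acceptor", "donor")),
      aberrant_boundaries = aberrant,
      case_kind = case_kind)
  })
}
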