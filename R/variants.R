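# Variant application, reference/alternate scan alignment, the seven-class
# splicing-event taxonomy, and the per-exon factor report.

VARIANT_KINDS <- c("SNV", "deletion", "insertion", "duplication")

EVENT_CLASSES <- c(
  "annotated_exon_disappears",
  "annotated_exon_score_change",
  "shared_ss_exon_score_change",
  "shared_ss_exon_disappears",
  "cryptic_exon_created_shared_ss",
  "exon_disappears",
  "cryptic_exon_created")

#' Construct a validated variant specification
#'
#' @param pos 1-based position on the reference sequence: the substituted
#'   base (SNV), the first deleted base (deletion), the base after which the
#'   insertion occurs (insertion), or the first base of the duplicated span
#'   (duplication).
#' @param ref reference allele ("" for insertions).
#' @param alt alternate allele ("" for deletions; for duplications the
#'   duplicated span, inserted once more after itself).
#' @param kind one of SNV, deletion, insertion, duplication; inferred from
#'   the alleles when missing.
#' @param id optional label.
#' @return object of class \code{variant_spec}.
#' @export
variant_spec <- function(pos, ref, alt, kind = NULL, id = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  check_dna(c(ref, alt)[nzchar(c(ref, alt))], "allele")
  if (is.null(kind)) {
    kind <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
    else if (nchar(alt) == 0L && nchar(ref) > 0L) "deletion"
    else if (nchar(ref) == 0L && nchar(alt) > 0L) "insertion"
    else stop("cannot infer variant kind from alleles", call. = FALSE)
  }
  kind <- match.arg(kind, VARIANT_KINDS)
  if (kind == "SNV" && ref == alt) {
    stop("SNV alleles are identical", call. = FALSE)
  }
  if (kind == "duplication" && !nzchar(ref)) {
    stop("duplication requires the duplicated span as ref", call. = FALSE)
  }
  structure(list(pos = as.integer(pos), ref = ref, alt = alt, kind = kind,
                 id = id %||% sprintf("%d%s>%s", pos,
                                      ifelse(nzchar(ref), ref, "-"),
                                      ifelse(nzchar(alt), alt, "-"))),
            class = "variant_spec")
}

#' Parse an intron-relative (IVS) variant string
#'
#' Resolves HGVS-like intronic notation such as \code{IVS2+2delC},
#' \code{IVS9+1G>A} or \code{IVS27+3_6dup(GGGT)} against an exon annotation.
#' Intron n lies between annotated exons n and n+1; \code{+k} counts from
#' the intron's first base, \code{-k} back from its last.
#'
#' @param x the IVS string.
#' @param exons annotation data.frame with 1-based inclusive \code{start},
#'   \code{end} columns ordered along the sequence.
#' @param seq optional reference sequence used to fill in deleted alleles
#'   not spelled out in the notation.
#' @return a \code{variant_spec}.
#' @export
parse_ivs_variant <- function(x, exons, seq = NULL) {
  m <- regmatches(x, regexec(
    "^IVS(\\d+)([+-]\\d+)(?:_(\\d+))?(?:(del|dup|ins)\\(?([ACGT]*)\\)?|([ACGT])>([ACGT]))$",
    x))[[1]]
  if (!length(m)) stop("cannot parse IVS notation: ", x, call. = FALSE)
  intron <- as.integer(m[2]); off1 <- as.integer(m[3])
  if (intron >= nrow(exons)) {
    stop("annotation has no intron ", intron, call. = FALSE)
  }
  intron_start <- exons$end[intron] + 1L       # 1-based first intronic base
  intron_end <- exons$start[intron + 1L] - 1L  # 1-based last intronic base
  resolve <- function(k) {
    if (k > 0) intron_start + k - 1L else intron_end + k + 1L
  }
  pos <- resolve(off1)
  op <- m[5]; payload <- m[6]
  if (nzchar(m[7])) {  # substitution form IVSn+kR>A
    return(variant_spec(pos, m[7], m[8], kind = "SNV", id = x))
  }
  span_end <- if (nzchar(m[4])) resolve(as.integer(m[4]) * sign(off1)) else NA
  width <- if (is.na(span_end)) max(nchar(payload), 1L) else span_end - pos + 1L
  ref <- payload
  if (!nzchar(ref)) {
    if (is.null(seq)) stop("need seq to resolve alleles for ", x, call. = FALSE)
    ref <- substr(as_seq_string(seq), pos, pos + width - 1L)
  }
  switch(op,
    del = variant_spec(pos, ref, "", kind = "deletion", id = x),
    dup = variant_spec(pos, ref, paste0(ref, ref), kind = "duplication",
                       id = x),
    ins = variant_spec(pos, "", ref, kind = "insertion", id = x),
    stop("unsupported IVS operation in ", x, call. = FALSE))
}

#' Apply a variant to a sequence
#'
#' Returns the edited sequence together with a monotone partial bijection
#' between reference and alternate coordinates (1-based; NA inside deleted
#' or inserted spans).
#'
#' @param seq reference sequence (character or \code{DNAString}).
#' @param variant a \code{variant_spec}; the ref allele is validated against
#'   the sequence.
#' @return list with \code{alt_seq}, \code{ref_to_alt} (integer vector over
#'   reference positions) and \code{alt_to_ref}.
#' @export
apply_variant <- function(seq, variant) {
  stopifnot(inherits(variant, "variant_spec"))
  seq <- as_seq_string(seq)
  n <- nchar(seq)
  p <- variant$pos
  ref <- variant$ref; alt <- variant$alt
  w_ref <- nchar(ref)
  if (variant$kind == "insertion") {
    if (p < 0L || p > n) stop("insertion point outside sequence", call. = FALSE)
  } else {
    if (p < 1L || p + w_ref - 1L > n) {
      stop("variant span outside sequence", call. = FALSE)
    }
    observed <- substr(seq, p, p + w_ref - 1L)
    if (observed != ref) {
      stop(sprintf("ref allele mismatch at %d: expected %s, sequence has %s",
                   p, ref, observed), call. = FALSE)
    }
  }
  if (variant$kind == "duplication" &&
      substr(alt, 1L, w_ref) != ref) {
    stop("duplication alt must begin with the duplicated span", call. = FALSE)
  }
  if (variant$kind == "insertion") {
    alt_seq <- paste0(substr(seq, 1L, p), alt, substr(seq, p + 1L, n))
    ref_to_alt <- c(seq_len(p), seq(p + nchar(alt) + 1L, length.out = n - p))
    alt_to_ref <- rep(NA_integer_, nchar(alt_seq))
    alt_to_ref[seq_len(p)] <- seq_len(p)
    alt_to_ref[seq(p + nchar(alt) + 1L, length.out = n - p)] <-
      seq(p + 1L, length.out = n - p)
  } else {
    alt_seq <- paste0(substr(seq, 1L, p - 1L), alt,
                      substr(seq, p + w_ref, n))
    n_alt <- nchar(alt_seq)
    ref_to_alt <- rep(NA_integer_, n)
    alt_to_ref <- rep(NA_integer_, n_alt)
    if (p > 1L) {
      ref_to_alt[seq_len(p - 1L)] <- seq_len(p - 1L)
      alt_to_ref[seq_len(p - 1L)] <- seq_len(p - 1L)
    }
    if (variant$kind == "SNV") {
      ref_to_alt[p] <- p
      alt_to_ref[p] <- p
    } else if (variant$kind == "duplication") {
      # The original span keeps its coordinates; the copy is unmapped.
      ref_to_alt[seq(p, length.out = w_ref)] <- seq(p, length.out = w_ref)
      alt_to_ref[seq(p, length.out = w_ref)] <- seq(p, length.out = w_ref)
    }
    tail_n <- n - (p + w_ref - 1L)
    if (tail_n > 0L) {
      shift <- nchar(alt) - w_ref
      ref_tail <- seq(p + w_ref, length.out = tail_n)
      ref_to_alt[ref_tail] <- ref_tail + shift
      alt_to_ref[ref_tail + shift] <- ref_tail
    }
  }
  list(alt_seq = alt_seq, ref_to_alt = ref_to_alt, alt_to_ref = alt_to_ref)
}

# Map a 0-based boundary position through a 1-based coordinate vector.
map_pos0 <- function(map_vec, pos0) {
  out <- map_vec[pos0 + 1L]
  out - 1L
}

#' Classify splicing differences between a reference and an alternate scan
#'
#' Reported exons of the two scans are aligned through the coordinate map
#' (an exon persists when both mapped boundaries match). Every change is
#' assigned exactly one of seven classes with precedence annotated exon
#' (both boundaries equal an annotated exon) over shared splice site
#' (exactly one boundary annotated) over generic: annotated exon disappears
#' / changes score; shared-SS exon changes score / disappears / is created;
#' exon disappears / cryptic exon created. Score change is the relative
#' change of the normalized exon score and must exceed
#' \code{score_change_threshold}; score changes of exons unrelated to any
#' annotated boundary are not events.
#'
#' @param ref_scan,alt_scan \code{scan_result}s from the same parameter
#'   snapshot.
#' @param coordinate_map as returned by \code{\link{apply_variant}}.
#' @param annotation data.frame of annotated exons with 1-based inclusive
#'   \code{start}, \code{end} (reference coordinates); may have zero rows.
#' @param score_change_threshold relative-change cutoff (default 0.02).
#' @param reported_only compare only exons at/above the report threshold
#'   (default TRUE).
#' @return data.frame of events: event_class, ref_acceptor, ref_donor,
#'   alt_acceptor, alt_donor (0-based; NA where absent), ref_score,
#'   alt_score, score_delta, n_annotated_boundaries.
#' @export
classify_events <- function(ref_scan, alt_scan, coordinate_map, annotation,
                            score_change_threshold = 0.02,
                            reported_only = TRUE) {
  ref <- ref_scan$exons; alt <- alt_scan$exons
  if (reported_only) {
    ref <- ref[ref$reported, , drop = FALSE]
    alt <- alt[alt$reported, , drop = FALSE]
  }
  ann_acc <- integer(0); ann_don <- integer(0)
  if (!is.null(annotation) && nrow(annotation)) {
    ann_acc <- annotation$start - 1L  # 0-based first exonic nt
    ann_don <- annotation$end        # 0-based first intronic nt
  }
  ref$map_acc <- map_pos0(coordinate_map$ref_to_alt, ref$acceptor_pos)
  ref$map_don <- map_pos0(coordinate_map$ref_to_alt, ref$donor_pos)
  alt$back_acc <- map_pos0(coordinate_map$alt_to_ref, alt$acceptor_pos)
  alt$back_don <- map_pos0(coordinate_map$alt_to_ref, alt$donor_pos)
  key <- function(a, d) paste(a, d, sep = ":")
  alt_keys <- key(alt$acceptor_pos, alt$donor_pos)
  ref_mapped_keys <- key(ref$map_acc, ref$map_don)
  match_alt <- match(ref_mapped_keys, alt_keys)
  match_alt[is.na(ref$map_acc) | is.na(ref$map_don)] <- NA
  matched_alt <- stats::na.omit(match_alt)

  n_ann <- function(acc0, don0) {
    (acc0 %in% ann_acc) + (don0 %in% ann_don)
  }
  events <- list()
  add <- function(class, ra = NA, rd = NA, aa = NA, ad = NA,
                  rs = NA, as = NA, delta = NA, nan = 0L) {
    events[[length(events) + 1L]] <<- data.frame(
      event_class = class, ref_acceptor = ra, ref_donor = rd,
      alt_acceptor = aa, alt_donor = ad, ref_score = rs, alt_score = as,
      score_delta = delta, n_annotated_boundaries = nan,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ref))) {
    nan <- n_ann(ref$acceptor_pos[i], ref$donor_pos[i])
    j <- match_alt[i]
    if (is.na(j)) {  # exon lost
      cls <- if (nan == 2L) "annotated_exon_disappears"
      else if (nan == 1L) "shared_ss_exon_disappears"
      else "exon_disappears"
      add(cls, ref$acceptor_pos[i], ref$donor_pos[i],
          rs = ref$normalized_score[i], nan = nan)
    } else {  # exon persists: score change?
      rs <- ref$normalized_score[i]; as <- alt$normalized_score[j]
      delta <- (as - rs) / rs
      if (abs(delta) > score_change_threshold) {
        cls <- if (nan == 2L) "annotated_exon_score_change"
        else if (nan == 1L) "shared_ss_exon_score_change"
        else NA_character_  # no taxonomy row for unanchored score changes
        if (!is.na(cls)) {
          add(cls, ref$acceptor_pos[i], ref$donor_pos[i],
              alt$acceptor_pos[j], alt$donor_pos[j], rs, as, delta, nan)
        }
      }
    }
  }
  for (j in seq_len(nrow(alt))) {
    if (j %in% matched_alt) next
    # annotated-boundary match assessed in reference coordinates
    nan <- n_ann(alt$back_acc[j], alt$back_don[j])
    cls <- if (nan >= 1L) "cryptic_exon_created_shared_ss"
    else "cryptic_exon_created"
    add(cls, aa = alt$acceptor_pos[j], ad = alt$donor_pos[j],
        as = alt$normalized_score[j], nan = nan)
  }
  out <- if (length(events)) do.call(rbind, events) else data.frame(
    event_class = character(0), ref_acceptor = integer(0),
    ref_donor = integer(0), alt_acceptor = integer(0),
    alt_donor = integer(0), ref_score = numeric(0), alt_score = numeric(0),
    score_delta = numeric(0), n_annotated_boundaries = integer(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Plain-text factor report for a scored exon
#'
#' Deterministic textual block listing the exon's boundaries, the sensor
#' evidence at each splice site, every resolved cis-element hit, the
#' competitor penalties, the length term, and the total and normalized
#' scores. The printed component LODs sum to the printed total.
#'
#' @param exon a \code{candidate_exon} from \code{\link{score_exon}}.
#' @return a single character string (the report).
#' @export
report_factors <- function(exon) {
  stopifnot(inherits(exon, "candidate_exon"))
  a <- exon$acceptor; d <- exon$donor
  lines <- c(
    sprintf("candidate exon %d-%d (1-based), length %d nt, donor kind %s",
            a$position + 1L, d$position, exon$length, d$kind),
    sprintf("  3'SS at %d: posterior %.4f, strength %d, LOD %+.4f",
            a$position + 1L, a$posterior, a$strength, exon$lod_acceptor),
    sprintf("  5'SS at %d: posterior %.4f, strength %d, LOD %+.4f",
            d$position, d$posterior, d$strength, exon$lod_donor),
    sprintf("  length term: LOD %+.4f", exon$lod_length))
  eh <- exon$element_hits
  lines <- c(lines, sprintf("  elements (%d resolved, LOD %+.4f):",
                            nrow(eh), exon$lod_elements))
  for (i in seq_len(nrow(eh))) {
    lines <- c(lines, sprintf("    %s %s at offset %+d: LOD %+.4f",
                              eh$element_class[i], eh$motif[i],
                              eh$offset[i], eh$lod[i]))
  }
  ch <- exon$competitor_hits
  n_comp <- if (is.null(ch)) 0L else nrow(ch)
  lines <- c(lines, sprintf("  competitors (%d, LOD %+.4f):",
                            n_comp, exon$lod_competitors))
  for (i in seq_len(n_comp)) {
    lines <- c(lines, sprintf("    %s at %d: posterior %.4f",
                              ch$kind[i], ch$position[i], ch$posterior[i]))
  }
  lines <- c(lines,
             sprintf("  total LOD %+.4f = %+.4f %+.4f %+.4f %+.4f %+.4f",
                     exon$total_lod, exon$lod_acceptor, exon$lod_donor,
                     exon$lod_length, exon$lod_elements,
                     exon$lod_competitors),
             sprintf("  normalized exon score %.4f",
                     exon$normalized_exon_score))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Per-class event counts and between-group ratios
#'
#' Tabulates splicing events by class for two or more groups and reports
#' the ratio of the first group's count to each other group's, rounded to
#' 2 decimal places; "-" where both counts are zero, "Inf" where only the
#' denominator is.
#'
#' @param events_by_group named list of event data.frames (or of character
#'   vectors of event classes).
#' @return data.frame with one row per event class: a count column per group
#'   and a ratio column per non-first group.
#' @export
enrichment_table <- function(events_by_group) {
  stopifnot(length(events_by_group) >= 2L)
  groups <- names(events_by_group) %||%
    paste0("group", seq_along(events_by_group))
  counts <- vapply(events_by_group, function(ev) {
    cls <- if (is.data.frame(ev)) ev$event_class else as.character(ev)
    vapply(EVENT_CLASSES, function(cl) sum(cls == cl), numeric(1))
  }, numeric(length(EVENT_CLASSES)))
  counts <- matrix(counts, nrow = length(EVENT_CLASSES),
                   dimnames = list(EVENT_CLASSES, groups))
  out <- data.frame(event_class = EVENT_CLASSES, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (g in groups[-1]) {
    num <- counts[, groups[1]]; den <- counts[, g]
    ratio <- ifelse(den == 0 & num == 0, "-",
                    ifelse(den == 0, "Inf",
                           sprintf("%.2f", round(num / den, 2))))
    out[[paste0("ratio_", groups[1], "_vs_", g)]] <- ratio
  }
  rownames(out) <- NULL
  out
}
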