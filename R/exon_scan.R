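# Candidate-exon enumeration, the full scanning pipeline, and the
# training-time pseudoexon extraction rules.
#
# Coordinates are 0-based internally: an exon paired from an acceptor call
# at a and a donor call at d occupies [a, d) and has length d - a. Reports
# are 1-based inclusive.

#' Enumerate admissible (acceptor, donor) pairs
#'
#' Every acceptor paired with every downstream donor whose distance lies in
#' \[min_len, max_len\] nt, boundary to boundary.
#'
#' @param sites splice-site call data.frame (see
#'   \code{\link{scan_splice_sites}}), position-sorted.
#' @param min_len,max_len admissible exon lengths in nt (defaults 6 and 399:
#'   longer than 5 nt and shorter than 400 nt).
#' @return data.frame with columns acceptor_idx, donor_idx (rows of
#'   \code{sites}) and length.
#' @export
enumerate_candidate_exons <- function(sites, min_len = 6L, max_len = 399L) {
  acc <- which(sites$kind == "acceptor")
  don <- which(sites$kind != "acceptor")
  if (!length(acc) || !length(don)) {
    return(data.frame(acceptor_idx = integer(0), donor_idx = integer(0),
                      length = integer(0)))
  }
  grid <- expand.grid(acceptor_idx = acc, donor_idx = don)
  len <- sites$position[grid$donor_idx] - sites$position[grid$acceptor_idx]
  keep <- len >= min_len & len <= max_len
  out <- grid[keep, , drop = FALSE]
  out$length <- len[keep]
  out <- out[order(out$acceptor_idx, out$donor_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Strong same-side sites near or inside an exon, excluding its own pair.
# Donors (GT or GC) compete with the exon's donor; acceptors with its
# acceptor.
find_competitors <- function(sites, acceptor_idx, donor_idx,
                             vicinity = 50L, min_posterior = 0.5) {
  a <- sites$position[acceptor_idx]
  d <- sites$position[donor_idx]
  cand <- setdiff(seq_len(nrow(sites)), c(acceptor_idx, donor_idx))
  if (!length(cand)) return(sites[0, , drop = FALSE])
  pos <- sites$position[cand]
  near <- pos >= a - vicinity & pos <= d + vicinity
  strong <- sites$posterior[cand] > min_posterior
  sites[cand[near & strong], , drop = FALSE]
}

#' Scan a sequence for candidate internal exons
#'
#' Full pipeline: apply the sensors, enumerate all admissible
#' (acceptor, donor) pairs, attach overlap-resolved cis-element hits and
#' competitor penalties, and score every candidate exon. All candidates are
#' retained in the result; those at or above \code{report_threshold}
#' (normalized exon score) are flagged as reported.
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param models list of sensors as for \code{\link{scan_splice_sites}}, or
#'   a \code{splice_model} bundle (profiles/length model/calibration are then
#'   taken from the bundle unless overridden).
#' @param profiles list of \code{cis_element_profile}s (may be empty).
#' @param length_model a \code{length_model} or NULL.
#' @param exon_calibration reference total-LOD distribution(s); see
#'   \code{\link{score_exon}}.
#' @param min_posterior sensor call threshold (default 0.01).
#' @param report_threshold normalized exon score below which candidates are
#'   omitted from reports (default 0.5).
#' @param min_len,max_len admissible exon lengths (defaults 6, 399).
#' @param competitor_scale,competitor_vicinity,competitor_min_posterior
#'   competitor-penalty knobs (defaults 0.5, 50 nt, 0.5).
#' @param sequence_id identifier used in reports.
#' @return object of class \code{scan_result}: sequence_id, sites, exons
#'   (data.frame sorted by descending normalized score, with a
#'   \code{reported} flag), parameters.
#' @export
scan_sequence <- function(seq, models, profiles = list(),
                          length_model = NULL, exon_calibration = NULL,
                          min_posterior = 0.01, report_threshold = 0.5,
                          min_len = 6L, max_len = 399L,
                          competitor_scale = 0.5, competitor_vicinity = 50L,
                          competitor_min_posterior = 0.5,
                          sequence_id = "seq") {
  if (inherits(models, "splice_model")) {
    bundle <- models
    models <- bundle$sensors
    if (missing(profiles)) profiles <- bundle$profiles
    if (is.null(length_model)) length_model <- bundle$length_model
    if (is.null(exon_calibration)) exon_calibration <- bundle$exon_calibration
  }
  seq <- as_seq_string(seq)
  sites <- scan_splice_sites(seq, models, min_posterior = min_posterior)
  pairs <- enumerate_candidate_exons(sites, min_len = min_len,
                                     max_len = max_len)
  params <- list(min_posterior = min_posterior,
                 report_threshold = report_threshold,
                 min_len = min_len, max_len = max_len,
                 competitor_scale = competitor_scale,
                 competitor_vicinity = competitor_vicinity,
                 competitor_min_posterior = competitor_min_posterior)
  # Pre-locate every profile motif once; per-exon lookups reuse these.
  motif_starts <- lapply(profiles, function(pr) {
    m <- gregexpr(pr$motif, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  })
  exons <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ai <- pairs$acceptor_idx[i]; di <- pairs$donor_idx[i]
    acceptor <- sites[ai, ]; donor <- sites[di, ]
    hits <- collect_element_hits(profiles, motif_starts, acceptor, donor)
    hits <- resolve_overlaps(hits)
    comp <- find_competitors(sites, ai, di,
                             vicinity = competitor_vicinity,
                             min_posterior = competitor_min_posterior)
    ex <- score_exon(acceptor, donor, element_hits = hits,
                     competitor_hits = comp, length_model = length_model,
                     exon_calibration = exon_calibration,
                     competitor_scale = competitor_scale,
                     min_len = min_len, max_len = max_len)
    exons[[i]] <- data.frame(
      acceptor_pos = acceptor$position, donor_pos = donor$position,
      donor_kind = donor$kind, length = ex$length,
      s3 = acceptor$strength, s5 = donor$strength,
      acceptor_posterior = acceptor$posterior,
      donor_posterior = donor$posterior,
      lod_acceptor = ex$lod_acceptor, lod_donor = ex$lod_donor,
      lod_length = ex$lod_length, lod_elements = ex$lod_elements,
      lod_competitors = ex$lod_competitors, total_lod = ex$total_lod,
      normalized_score = ex$normalized_exon_score,
      n_elements = nrow(ex$element_hits),
      n_competitors = if (is.null(comp)) 0L else nrow(comp),
      stringsAsFactors = FALSE)
  }
  exons <- if (length(exons)) do.call(rbind, exons) else empty_exon_table()
  exons$reported <- exons$normalized_score >= report_threshold
  ord <- order(-exons$normalized_score, exons$acceptor_pos, exons$donor_pos)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(sequence_id = sequence_id, sites = sites, exons = exons,
                 parameters = params),
            class = "scan_result")
}

empty_exon_table <- function() {
  data.frame(acceptor_pos = integer(0), donor_pos = integer(0),
             donor_kind = character(0), length = integer(0),
             s3 = integer(0), s5 = integer(0),
             acceptor_posterior = numeric(0), donor_posterior = numeric(0),
             lod_acceptor = numeric(0), lod_donor = numeric(0),
             lod_length = numeric(0), lod_elements = numeric(0),
             lod_competitors = numeric(0), total_lod = numeric(0),
             normalized_score = numeric(0), n_elements = integer(0),
             n_competitors = integer(0), stringsAsFactors = FALSE)
}

# Element hits for one exon: near_5SS profiles anchor on the donor,
# near_3SS on the acceptor; hits are admitted wherever the profile retains
# the offset, on either side of the boundary.
collect_element_hits <- function(profiles, motif_starts, acceptor, donor) {
  out <- vector("list", length(profiles))
  for (j in seq_along(profiles)) {
    pr <- profiles[[j]]
    starts <- motif_starts[[j]]
    if (!length(starts)) next
    anchor <- if (pr$side == "near_5SS") donor$position else acceptor$position
    offset <- starts - anchor
    lod <- profile_lod_at(pr, offset)
    keep <- !is.na(lod)
    if (!any(keep)) next
    out[[j]] <- data.frame(motif = pr$motif, start = starts[keep],
                           end = starts[keep] + nchar(pr$motif),
                           offset = offset[keep], lod = lod[keep],
                           element_class = pr$element_class,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) empty_hits() else out
}

#' @export
print.scan_result <- function(x, ...) {
  rep_n <- sum(x$exons$reported)
  cat(sprintf("scan of %s: %d site calls, %d candidate exons (%d reported)\n",
              x$sequence_id, nrow(x$sites), nrow(x$exons), rep_n))
  if (rep_n) {
    top <- utils::head(x$exons[x$exons$reported, ], 5)
    cat("  top reported exons (1-based start-end, score):\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %d-%d  %s  score %.3f  total LOD %+.2f\n",
                  top$acceptor_pos[i] + 1L, top$donor_pos[i],
                  top$donor_kind[i], top$normalized_score[i],
                  top$total_lod[i]))
    }
  }
  invisible(x)
}

#' Extract pseudoexons from an intron for decoy training
#'
#' Pseudoexons are intervals between decoy acceptor and donor calls in the
#' intron interior. Retained records must have a posterior sum above
#' \code{min_score_sum}, a length longer than 5 and shorter than 400 nt,
#' both flanks of \code{flank} nt inside the interior (the first and last
#' \code{edge_exclusion} nt of the intron are excluded to avoid
#' exon-proximal element bias), and a unique flank/body context (exact
#' duplicates are discarded).
#'
#' @param intron_seq intronic DNA sequence.
#' @param models sensors as for \code{\link{scan_splice_sites}}.
#' @param min_score_sum minimum acceptor+donor posterior sum (default 0.05).
#' @param edge_exclusion nt trimmed from each intron end (default 150).
#' @param flank required flank length around each pseudoexon (default 205).
#' @param min_len,max_len admissible pseudoexon lengths (defaults 6, 399).
#' @return data.frame of records: acceptor_pos, donor_pos (0-based), length,
#'   acceptor_posterior, donor_posterior, score_sum, upstream_flank, body,
#'   downstream_flank.
#' @export
extract_pseudoexons <- function(intron_seq, models, min_score_sum = 0.05,
                                edge_exclusion = 150L, flank = 205L,
                                min_len = 6L, max_len = 399L) {
  intron_seq <- as_seq_string(intron_seq)
  n <- nchar(intron_seq)
  empty <- data.frame(acceptor_pos = integer(0), donor_pos = integer(0),
                      length = integer(0), acceptor_posterior = numeric(0),
                      donor_posterior = numeric(0), score_sum = numeric(0),
                      upstream_flank = character(0), body = character(0),
                      downstream_flank = character(0),
                      stringsAsFactors = FALSE)
  if (n <= 2L * edge_exclusion) return(empty)
  sites <- scan_splice_sites(intron_seq, models, min_posterior = 0)
  interior <- sites$position >= edge_exclusion &
    sites$position <= n - edge_exclusion
  sites <- sites[interior, , drop = FALSE]
  pairs <- enumerate_candidate_exons(sites, min_len = min_len,
                                     max_len = max_len)
  if (!nrow(pairs)) return(empty)
  a <- sites$position[pairs$acceptor_idx]
  d <- sites$position[pairs$donor_idx]
  pa <- sites$posterior[pairs$acceptor_idx]
  pd <- sites$posterior[pairs$donor_idx]
  keep <- (pa + pd) > min_score_sum &
    (a - flank) >= edge_exclusion & (d + flank) <= n - edge_exclusion
  if (!any(keep)) return(empty)
  a <- a[keep]; d <- d[keep]; pa <- pa[keep]; pd <- pd[keep]
  up <- substring(intron_seq, a - flank + 1L, a)
  body <- substring(intron_seq, a + 1L, d)
  down <- substring(intron_seq, d + 1L, d + flank)
  dup <- duplicated(paste(up, down, sep = "|")) | duplicated(body)
  out <- data.frame(acceptor_pos = a, donor_pos = d, length = d - a,
                    acceptor_posterior = pa, donor_posterior = pd,
                    score_sum = pa + pd, upstream_flank = up, body = body,
                    downstream_flank = down, stringsAsFactors = FALSE)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export scan results as GFF3
#'
#' Writes splice-site calls (\code{splice_acceptor}, \code{splice_donor})
#' and reported candidate exons (\code{predicted_exon}) with the component
#' LODs as attributes. Coordinates are 1-based inclusive; exon features span
#' the exon body.
#'
#' @param result a \code{scan_result}.
#' @param path output file.
#' @param reported_only write only exons at or above the report threshold
#'   (default TRUE).
#' @return the path, invisibly.
#' @export
export_scan_gff3 <- function(result, path, reported_only = TRUE) {
  stopifnot(inherits(result, "scan_result"))
  sites <- result$sites
  site_type <- ifelse(sites$kind == "acceptor", "splice_acceptor",
                      "splice_donor")
  # A site feature marks the two intronic anchor nucleotides.
  site_start <- ifelse(sites$kind == "acceptor",
                       sites$position - 1L, sites$position + 1L)
  gr_sites <- GenomicRanges::GRanges(
    seqnames = result$sequence_id,
    ranges = IRanges::IRanges(start = site_start, width = 2L),
    type = site_type, score = sites$normalized_score,
    kind = sites$kind, posterior = round(sites$posterior, 6),
    strength = sites$strength)
  ex <- result$exons
  if (reported_only) ex <- ex[ex$reported, , drop = FALSE]
  gr_ex <- GenomicRanges::GRanges(
    seqnames = rep(result$sequence_id, nrow(ex)),
    ranges = IRanges::IRanges(start = ex$acceptor_pos + 1L,
                              end = ex$donor_pos),
    type = rep("predicted_exon", nrow(ex)),
    score = ex$normalized_score, donor_kind = ex$donor_kind,
    lod_acceptor = round(ex$lod_acceptor, 4),
    lod_donor = round(ex$lod_donor, 4),
    lod_length = round(ex$lod_length, 4),
    lod_elements = round(ex$lod_elements, 4),
    lod_competitors = round(ex$lod_competitors, 4),
    total_lod = round(ex$total_lod, 4))
  rtracklayer::export(c(gr_sites, gr_ex), path, format = "gff3")
  invisible(path)
}
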