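# Positional LOD profiles for cis-acting splicing elements (ESE/ESS/ISE/ISS)
# and overlap resolution of element hits.
#
# A profile compares how often a motif starts at each offset relative to a
# splice signal in true-site flank contexts versus decoy-site contexts:
# LOD(i) = log2( (ct(i)+pc)/N_true / ((cd(i)+pc)/N_decoy) ), optionally
# smoothed by a centered moving average.

ELEMENT_CLASSES <- c("ESE", "ESS", "ISE", "ISS")

#' Build a positional LOD profile for one cis-regulatory motif
#'
#' Counts exact-match occurrences of \code{motif} at every start offset in
#' aligned true-site and decoy-site flank contexts (the splice signal sits at
#' a fixed column of every context) and converts the two occurrence
#' frequencies into a per-offset log2 odds curve, pseudocount-smoothed and
#' averaged over a centered window.
#'
#' @param motif element motif (typically 7-8 nt).
#' @param element_class one of ESE, ESS, ISE, ISS.
#' @param side which splice signal the contexts are anchored to
#'   (\code{"near_5SS"} or \code{"near_3SS"}).
#' @param true_contexts,decoy_contexts character vectors of equal-length
#'   aligned flank sequences.
#' @param ss_column 1-based column of the contexts corresponding to the
#'   splice signal (offset 0). Offsets are start positions minus this column.
#' @param smoothing_window odd moving-average width in nt (1 = none).
#' @param pseudocount additive count regularizer (default 0.5).
#' @param strength_class optional site-strength class the contexts were
#'   conditioned on (kept as metadata).
#' @return object of class \code{cis_element_profile} with fields motif,
#'   element_class, side, strength_class, offsets, lod, support_true,
#'   support_decoy, n_true, n_decoy.
#' @export
build_lod_profile <- function(motif, element_class, side,
                              true_contexts, decoy_contexts,
                              ss_column = 1L,
                              smoothing_window = 11L, pseudocount = 0.5,
                              strength_class = NA_integer_) {
  element_class <- match.arg(element_class, ELEMENT_CLASSES)
  side <- match.arg(side, c("near_5SS", "near_3SS"))
  motif <- toupper(motif)
  if (length(true_contexts) == 0L || length(decoy_contexts) == 0L) {
    stop("insufficient data: need contexts on both sides", call. = FALSE)
  }
  if (smoothing_window %% 2L != 1L) {
    stop("smoothing_window must be odd", call. = FALSE)
  }
  len <- unique(nchar(c(true_contexts, decoy_contexts)))
  if (length(len) != 1L) {
    stop("contexts must share one alignment length", call. = FALSE)
  }
  n_pos <- len - nchar(motif) + 1L
  if (n_pos < 1L) stop("motif longer than contexts", call. = FALSE)
  ct <- count_starts(true_contexts, motif, n_pos)
  cd <- count_starts(decoy_contexts, motif, n_pos)
  n_t <- length(true_contexts); n_d <- length(decoy_contexts)
  lod <- log2(((ct + pseudocount) / n_t) / ((cd + pseudocount) / n_d))
  # with pseudocount 0 an offset unseen on either side has no defined LOD
  lod[!is.finite(lod)] <- NA_real_
  if (smoothing_window > 1L) lod <- moving_average(lod, smoothing_window)
  structure(
    list(motif = motif, element_class = element_class, side = side,
         strength_class = strength_class,
         offsets = seq_len(n_pos) - ss_column,
         lod = lod, support_true = ct, support_decoy = cd,
         n_true = n_t, n_decoy = n_d,
         smoothing_window = smoothing_window, pseudocount = pseudocount),
    class = "cis_element_profile")
}

# Per-start-position occurrence counts of a fixed motif across sequences.
count_starts <- function(seqs, motif, n_pos) {
  counts <- numeric(n_pos)
  hits <- gregexpr(motif, seqs, fixed = TRUE)
  for (h in hits) {
    if (h[1] == -1L) next
    h <- h[h <= n_pos]
    counts[h] <- counts[h] + 1
  }
  counts
}

# Centered moving average with shrinking windows at the edges; NA entries
# are excluded from the averages (all-NA windows stay NA).
moving_average <- function(x, w) {
  half <- (w - 1L) / 2L
  n <- length(x)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  cs <- cumsum(c(0, x0))
  ck <- cumsum(c(0L, ok))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  m <- ck[hi + 1L] - ck[lo]
  out <- (cs[hi + 1L] - cs[lo]) / m
  out[m == 0L] <- NA_real_
  out
}

#' @export
print.cis_element_profile <- function(x, ...) {
  cat(sprintf("cis-element LOD profile: %s (%s, %s), offsets %d..%d\n",
              x$motif, x$element_class, x$side,
              min(x$offsets), max(x$offsets)))
  cat(sprintf("  built from %d true / %d decoy contexts; peak LOD %.2f at %+d\n",
              x$n_true, x$n_decoy, max(x$lod), x$offsets[which.max(x$lod)]))
  invisible(x)
}

#' Look up a profile's LOD at given offsets
#'
#' @param profile a \code{cis_element_profile}.
#' @param offsets integer offsets relative to the anchoring splice signal.
#' @return numeric LOD values; NA where the offset is not retained.
#' @export
profile_lod_at <- function(profile, offsets) {
  idx <- match(offsets, profile$offsets)
  profile$lod[idx]
}

#' Scan a region for cis-element hits anchored to a splice-site call
#'
#' Reports one hit per exact occurrence of each profile's motif inside
#' \code{region} whose start offset (relative to \code{anchor_position}) has
#' a retained LOD value in the profile.
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param region 0-based half-open interval c(start, end) to scan.
#' @param profiles list of \code{cis_element_profile}s.
#' @param anchor_position 0-based position of the anchoring splice signal
#'   (a donor's first intronic nt or an acceptor's first exonic nt).
#' @return data.frame of hits: motif, start, end (0-based half-open),
#'   offset, lod, element_class.
#' @export
scan_elements <- function(seq, region, profiles, anchor_position) {
  seq <- as_seq_string(seq)
  stopifnot(length(region) == 2L, region[1] >= 0, region[2] <= nchar(seq))
  if (inherits(profiles, "cis_element_profile")) profiles <- list(profiles)
  sub <- substr(seq, region[1] + 1L, region[2])
  out <- lapply(profiles, function(pr) {
    m <- gregexpr(pr$motif, sub, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    start0 <- region[1] + as.integer(m) - 1L
    offset <- start0 - anchor_position
    lod <- profile_lod_at(pr, offset)
    keep <- !is.na(lod)
    if (!any(keep)) return(NULL)
    data.frame(motif = pr$motif, start = start0[keep],
               end = start0[keep] + nchar(pr$motif),
               offset = offset[keep], lod = lod[keep],
               element_class = pr$element_class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty_hits()
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(motif = character(0), start = integer(0), end = integer(0),
             offset = integer(0), lod = numeric(0),
             element_class = character(0), stringsAsFactors = FALSE)
}

#' Resolve overlapping element hits
#'
#' Enhancing (positive-LOD) and silencing (negative-LOD) hits are resolved
#' independently: within each sign class, overlapping hits are reduced
#' greedily by descending |LOD| (ties: leftmost start, then motif) so that
#' every surviving set is overlap-free and every discarded hit overlaps a
#' surviving hit of larger |LOD|. An enhancer and a silencer may both survive
#' while overlapping each other.
#'
#' @param hits data.frame of hits as returned by \code{\link{scan_elements}}.
#' @return the surviving subset of \code{hits}, ordered by start.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  pos <- resolve_one_sign(hits[hits$lod >= 0, , drop = FALSE])
  neg <- resolve_one_sign(hits[hits$lod < 0, , drop = FALSE])
  out <- rbind(pos, neg)
  out <- out[order(out$start, out$end, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_one_sign <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-abs(hits$lod), hits$start, hits$motif)
  hits <- hits[ord, , drop = FALSE]
  kept <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ki <- which(kept)
    if (!length(ki) ||
        !any(intervals_overlap(hits$start[i], hits$end[i],
                               hits$start[ki], hits$end[ki]))) {
      kept[i] <- TRUE
    }
  }
  hits[kept, , drop = FALSE]
}

#' Total element evidence of a resolved hit set
#'
#' @param resolved_hits overlap-resolved hits.
#' @return the arithmetic sum of the hits' LOD contributions (0 when empty).
#' @export
element_lod_sum <- function(resolved_hits) {
  if (nrow(resolved_hits) == 0L) return(0)
  sum(resolved_hits$lod)
}

#' The built-in demonstration element set
#'
#' A minimal motif catalog used in examples and tests: two poly-G family
#' intronic splicing enhancers and the exonic core of a strong canonical
#' donor, which behaves as a competitor (depleted near true donors).
#'
#' @return data.frame with columns motif, element_class, side.
#' @export
demo_element_motifs <- function() {
  data.frame(
    motif = c("GGGGTGGG", "CGGGGGCG", "AAGGTAA"),
    element_class = c("ISE", "ISE", "ESS"),
    side = c("near_5SS", "near_5SS", "near_5SS"),
    stringsAsFactors = FALSE)
}
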