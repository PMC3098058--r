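# Exon-boundary sensitivity/specificity and the aberrant-splicing
# correctness convention.

#' Sensitivity and specificity over exon boundaries
#'
#' Boundaries are (position, side) pairs; a predicted boundary is true when
#' it matches an annotated boundary exactly (configurable slack for
#' exploratory use). Sn = TE/AE and Sp = TE/PE where TE counts correctly
#' predicted boundaries, AE annotated boundaries and PE predicted
#' boundaries; 0/0 is reported as NA (undefined), not 0.
#'
#' @param predicted,annotated data.frames with columns \code{position}
#'   (0-based) and \code{side} ("acceptor"/"donor"); duplicates are dropped.
#' @param slack matching tolerance in nt (default 0 = exact).
#' @return object of class \code{eval_result}: TE, AE, PE, Sn, Sp.
#' @export
compute_sn_sp <- function(predicted, annotated, slack = 0L) {
  pk <- unique(paste(predicted$position, predicted$side))
  ak <- unique(paste(annotated$position, annotated$side))
  PE <- length(pk); AE <- length(ak)
  if (slack == 0L) {
    TE <- sum(pk %in% ak)
  } else {
    pu <- unique(predicted[, c("position", "side")])
    au <- unique(annotated[, c("position", "side")])
    TE <- sum(vapply(seq_len(nrow(pu)), function(i) {
      any(au$side == pu$side[i] &
            abs(au$position - pu$position[i]) <= slack)
    }, logical(1)))
  }
  if (AE == 0L) warning("no annotated boundaries; Sn undefined")
  structure(list(TE = TE, AE = AE, PE = PE,
                 Sn = if (AE > 0L) TE / AE else NA_real_,
                 Sp = if (PE > 0L) TE / PE else NA_real_),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("exon boundaries: TE %d / AE %d / PE %d;  Sn %.4f  Sp %.4f\n",
              x$TE, x$AE, x$PE, x$Sn, x$Sp))
  invisible(x)
}

#' Boundary table of a scan result
#'
#' @param result a \code{scan_result}.
#' @param reported_only use only reported exons (default TRUE).
#' @return data.frame with columns position (0-based) and side.
#' @export
scan_boundaries <- function(result, reported_only = TRUE) {
  ex <- result$exons
  if (reported_only) ex <- ex[ex$reported, , drop = FALSE]
  data.frame(
    position = c(ex$acceptor_pos, ex$donor_pos),
    side = rep(c("acceptor", "donor"), each = nrow(ex)),
    stringsAsFactors = FALSE)
}

#' Sensitivity/specificity sweep over the score threshold
#'
#' Recomputes boundary Sn and Sp at every distinct normalized exon score of
#' the scan(s), tracing the operating curve.
#'
#' @param exons candidate-exon table (one scan's \code{$exons}, or several
#'   rbound together).
#' @param annotated annotated boundary table (see
#'   \code{\link{compute_sn_sp}}).
#' @return data.frame with threshold, TE, AE, PE, Sn, Sp, one row per
#'   distinct threshold (descending).
#' @export
threshold_sweep <- function(exons, annotated) {
  thr <- sort(unique(exons$normalized_score), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    sel <- exons[exons$normalized_score >= t, , drop = FALSE]
    pred <- data.frame(
      position = c(sel$acceptor_pos, sel$donor_pos),
      side = rep(c("acceptor", "donor"), each = nrow(sel)))
    r <- compute_sn_sp(pred, annotated)
    data.frame(threshold = t, TE = r$TE, AE = r$AE, PE = r$PE,
               Sn = r$Sn, Sp = r$Sp)
  })
  do.call(rbind, rows)
}

#' Prediction accuracy as a percentage
#'
#' @param correct,incorrect case counts.
#' @return 100 * correct / (correct + incorrect), rounded to 2 decimals.
#' @export
accuracy <- function(correct, incorrect) {
  total <- correct + incorrect
  if (total <= 0) stop("accuracy undefined for zero cases", call. = FALSE)
  round(100 * correct / total, 2)
}

#' Construct an aberrant-splicing test case
#'
#' @param seq reference sequence.
#' @param variant a \code{variant_spec}.
#' @param annotation annotated exons (1-based start/end data.frame).
#' @param original_boundaries data.frame (position, side), 0-based: the
#'   annotated exon boundaries the mutation disturbs.
#' @param aberrant_boundaries data.frame (position, side), 0-based reference
#'   coordinates: the boundary/boundaries of the aberrant isoform.
#' @param case_kind "cryptic_SS" (one boundary shifts), "cryptic_exon"
#'   (a new exon with two new boundaries) or "other".
#' @return object of class \code{aberrant_case}.
#' @export
aberrant_case <- function(seq, variant, annotation, original_boundaries,
                          aberrant_boundaries,
                          case_kind = c("cryptic_SS", "cryptic_exon", "other")) {
  case_kind <- match.arg(case_kind)
  if (case_kind == "cryptic_exon" && nrow(aberrant_boundaries) < 2L) {
    stop("cryptic_exon cases need both aberrant boundaries", call. = FALSE)
  }
  structure(list(seq = as_seq_string(seq), variant = variant,
                 annotation = annotation,
                 original_boundaries = original_boundaries,
                 aberrant_boundaries = aberrant_boundaries,
                 case_kind = case_kind),
            class = "aberrant_case")
}

#' Score an aberrant-splicing case as correctly predicted or not
#'
#' A prediction is correct when the event list reproduces the annotated
#' boundary change: an activation event (a created exon, or a persisting
#' exon whose score increases) must carry exactly the annotated aberrant
#' boundary set -- both boundaries, for cryptic-exon cases -- and, for
#' cryptic-SS cases, a loss event (a disappearing exon or a score decrease)
#' must carry the original annotated boundary.
#'
#' @param case an \code{aberrant_case}.
#' @param events event table from \code{\link{classify_events}} run on the
#'   case (alt-side coordinates already mapped back to reference where the
#'   caller compares them; this function compares reference coordinates).
#' @param coordinate_map the map returned by \code{\link{apply_variant}}
#'   for the case's variant, used to express alt exon boundaries in
#'   reference coordinates.
#' @return TRUE (correct) or FALSE (incorrect).
#' @export
score_aberrant_case <- function(case, events, coordinate_map) {
  stopifnot(inherits(case, "aberrant_case"))
  if (!nrow(events)) return(FALSE)
  created <- events$event_class %in%
    c("cryptic_exon_created", "cryptic_exon_created_shared_ss")
  gained <- events$event_class %in%
    c("annotated_exon_score_change", "shared_ss_exon_score_change") &
    !is.na(events$score_delta) & events$score_delta > 0
  lost <- events$event_class %in%
    c("annotated_exon_disappears", "shared_ss_exon_disappears",
      "exon_disappears")
  weakened <- events$event_class %in%
    c("annotated_exon_score_change", "shared_ss_exon_score_change") &
    !is.na(events$score_delta) & events$score_delta < 0

  # Activation-side boundaries in reference coordinates.
  act_rows <- which(created | gained)
  has_aberrant <- any(vapply(act_rows, function(i) {
    acc <- events$alt_acceptor[i]; don <- events$alt_donor[i]
    if (!is.na(acc)) acc <- map_pos0(coordinate_map$alt_to_ref, acc)
    if (!is.na(don)) don <- map_pos0(coordinate_map$alt_to_ref, don)
    bounds <- data.frame(position = c(acc, don),
                         side = c("acceptor", "donor"))
    want <- case$aberrant_boundaries
    all(vapply(seq_len(nrow(want)), function(k) {
      any(!is.na(bounds$position) &
            bounds$position == want$position[k] &
            bounds$side == want$side[k])
    }, logical(1)))
  }, logical(1)))
  if (!has_aberrant) return(FALSE)
  if (case$case_kind == "cryptic_exon") return(TRUE)
  loss_rows <- which(lost | weakened)
  orig <- case$original_boundaries
  any(vapply(loss_rows, function(i) {
    bounds <- data.frame(position = c(events$ref_acceptor[i],
                                      events$ref_donor[i]),
                         side = c("acceptor", "donor"))
    any(vapply(seq_len(nrow(orig)), function(k) {
      any(!is.na(bounds$position) &
            bounds$position == orig$position[k] &
            bounds$side == orig$side[k])
    }, logical(1)))
  }, logical(1)))
}
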