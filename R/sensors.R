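# Bayesian oligonucleotide splice-site sensors.
#
# A sensor is a pair of oligo count tables (true splice sites vs decoy
# splice-like signals) over a fixed window around the intron boundary.
# With the prior and the likelihoods both estimated from the pooled counts,
# the Bayesian posterior that an oligo is a functional site reduces to
# t / (t + d), where t and d are the oligo's true and decoy counts.

SENSOR_KINDS <- c("donor_GT", "donor_GC", "acceptor")

# Intron-anchor dinucleotide for each sensor kind.
sensor_anchor <- function(sensor_kind) {
  switch(sensor_kind,
         donor_GT = "GT",
         donor_GC = "GC",
         acceptor = "AG",
         stop("unknown sensor kind: ", sensor_kind, call. = FALSE))
}

# Default windows: donors read 3 exonic + 6 intronic nt (9-mers); acceptors
# read 18 intronic + 3 exonic nt (covers the polypyrimidine tract).
default_window <- function(sensor_kind) {
  if (sensor_kind == "acceptor") c(upstream_nt = 18L, downstream_nt = 3L)
  else c(upstream_nt = 3L, downstream_nt = 6L)
}

# 1-based offset of the anchor dinucleotide within the oligo.
anchor_offset <- function(model) {
  if (model$sensor_kind == "acceptor") {
    # AG occupies the last two intronic positions.
    as.integer(model$window[["upstream_nt"]]) - 1L
  } else {
    # GT/GC opens the intron right after the exonic prefix.
    as.integer(model$window[["upstream_nt"]]) + 1L
  }
}

new_oligo_count_model <- function(sensor_kind, window, true_counts, decoy_counts,
                                  amplification_factor = 1,
                                  calibration = NULL, strength_breaks = NULL,
                                  pseudocount = 0) {
  model <- structure(
    list(sensor_kind = sensor_kind,
         window = window,
         true_counts = true_counts,
         decoy_counts = decoy_counts,
         n_true_total = sum(true_counts),
         n_decoy_total = sum(decoy_counts),
         amplification_factor = amplification_factor,
         calibration = calibration,
         strength_breaks = strength_breaks,
         pseudocount = pseudocount),
    class = "oligo_count_model")
  validate_oligo_count_model(model)
}

validate_oligo_count_model <- function(model) {
  k <- sum(model$window)
  oligos <- c(names(model$true_counts), names(model$decoy_counts))
  if (length(oligos) == 0L) stop("model has no counts", call. = FALSE)
  if (any(nchar(oligos) != k)) {
    stop("oligo length differs from window size ", k, call. = FALSE)
  }
  anc <- sensor_anchor(model$sensor_kind)
  off <- anchor_offset(model)
  if (!all(substr(oligos, off, off + 1L) == anc)) {
    stop(sprintf("all %s oligos must carry %s at the intron boundary",
                 model$sensor_kind, anc), call. = FALSE)
  }
  if (!isTRUE(all.equal(model$n_true_total, sum(model$true_counts))) ||
      !isTRUE(all.equal(model$n_decoy_total, sum(model$decoy_counts)))) {
    stop("count totals out of sync", call. = FALSE)
  }
  if (!is.null(model$calibration)) {
    cal <- model$calibration
    if (is.unsorted(cal$posterior) || is.unsorted(cal$normalized) ||
        any(cal$normalized < 0 | cal$normalized > 1)) {
      stop("calibration must be non-decreasing into [0,1]", call. = FALSE)
    }
  }
  model
}

#' @export
print.oligo_count_model <- function(x, ...) {
  cat(sprintf("Bayesian splice-site sensor (%s), window %d+%d nt\n",
              x$sensor_kind, x$window[[1]], x$window[[2]]))
  cat(sprintf("  true oligos: %d (total %d); decoy oligos: %d (total %d)\n",
              length(x$true_counts), x$n_true_total,
              length(x$decoy_counts), x$n_decoy_total))
  cat(sprintf("  decoy amplification: %.3f; calibration anchors: %d\n",
              x$amplification_factor,
              if (is.null(x$calibration)) 0L else nrow(x$calibration)))
  invisible(x)
}

#' Train a Bayesian splice-site sensor from true and decoy site oligos
#'
#' Tallies fixed-length oligonucleotides observed at annotated splice sites
#' and at decoy splice-like signals into a count model whose posterior is
#' t/(t+d). Decoy counts may be amplified by a constant factor when the decoy
#' collection under-samples the corpus the true sites came from; amplified
#' counts are rounded half-up with a floor of one for observed oligos.
#'
#' @param true_sites character vector of site oligos (equal length, window
#'   around the intron boundary; see \code{window}).
#' @param decoy_sites character vector of decoy oligos, same length.
#' @param sensor_kind one of \code{"donor_GT"}, \code{"donor_GC"},
#'   \code{"acceptor"}.
#' @param amplification_factor decoy count multiplier, \eqn{\ge 1}.
#' @param window integer pair (upstream_nt, downstream_nt) around the intron
#'   boundary; defaults to 3+6 for donors and 18+3 for acceptors.
#' @param pseudocount additive count used for oligos unseen in both tables
#'   (default 0: such oligos get posterior 0).
#' @param n_bins number of discrete strength bins (default 5).
#' @return an object of class \code{oligo_count_model}.
#' @examples
#' m <- train_oligo_model(rep("CAGGTAAGT", 3), "AAGGTGGGT", "donor_GT")
#' site_posterior(m, "CAGGTAAGT")
#' @export
train_oligo_model <- function(true_sites, decoy_sites, sensor_kind,
                              amplification_factor = 1,
                              window = default_window(sensor_kind),
                              pseudocount = 0, n_bins = 5L) {
  sensor_kind <- match.arg(sensor_kind, SENSOR_KINDS)
  if (length(true_sites) == 0L) {
    stop("insufficient data: no true sites supplied", call. = FALSE)
  }
  if (amplification_factor < 1) {
    stop("amplification_factor must be >= 1", call. = FALSE)
  }
  true_sites <- toupper(true_sites)
  decoy_sites <- toupper(decoy_sites)
  check_dna(c(true_sites, decoy_sites), "site oligos")
  k <- sum(window)
  lens <- unique(nchar(c(true_sites, decoy_sites)))
  if (length(lens) != 1L || lens != k) {
    stop(sprintf("length mismatch: oligos must all be %d nt (saw: %s)",
                 k, paste(lens, collapse = ", ")), call. = FALSE)
  }
  true_counts <- table_counts(true_sites)
  decoy_counts <- table_counts(decoy_sites)
  if (amplification_factor != 1 && length(decoy_counts)) {
    decoy_counts <- pmax(round_half_up(decoy_counts * amplification_factor), 1)
  }
  model <- new_oligo_count_model(sensor_kind, window, true_counts, decoy_counts,
                                 amplification_factor = amplification_factor,
                                 pseudocount = pseudocount)
  # Self-calibration: normalized score = percentile of the posterior among
  # the training true sites (their own normalization histogram).
  p_true <- site_posterior(model, names(model$true_counts))
  ord <- order(p_true)
  w <- as.numeric(model$true_counts)[ord]
  cal <- data.frame(posterior = p_true[ord],
                    normalized = cumsum(w) / sum(w))
  cal <- cal[!duplicated(cal$posterior, fromLast = TRUE), , drop = FALSE]
  model$calibration <- cal
  norm_true <- normalize_score(model, p_true)
  model$strength_breaks <- strength_breaks(rep(norm_true, model$true_counts),
                                           n_bins = n_bins)
  validate_oligo_count_model(model)
}

table_counts <- function(x) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(x)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Posterior probability that an oligo is a functional splice site
#'
#' Evaluates the sensor's Bayesian posterior t/(t+d) for one or more oligos,
#' where t and d are the model's true-site and decoy counts (optionally
#' inflated by the model's pseudocount). Oligos unseen on both sides score
#' the pseudocount posterior (0 when the pseudocount is 0).
#'
#' @param model an \code{oligo_count_model}.
#' @param oligo character vector of oligos matching the model window.
#' @return numeric vector of posteriors in \[0, 1\].
#' @export
site_posterior <- function(model, oligo) {
  stopifnot(inherits(model, "oligo_count_model"))
  oligo <- toupper(oligo)
  k <- sum(model$window)
  if (any(nchar(oligo) != k)) {
    stop("oligo length must equal the model window (", k, " nt)", call. = FALSE)
  }
  check_dna(oligo, "oligo")
  if (any(grepl("N", oligo, fixed = TRUE))) {
    stop("oligo contains N; posterior undefined", call. = FALSE)
  }
  t <- unname(model$true_counts[oligo]); t[is.na(t)] <- 0
  d <- unname(model$decoy_counts[oligo]); d[is.na(d)] <- 0
  a <- model$pseudocount
  tot <- t + d + 2 * a
  p <- ifelse(tot > 0, (t + a) / tot, 0)
  p
}

#' Map a raw posterior onto the sensor's normalized 0-1 score scale
#'
#' Monotone piecewise-linear interpolation through the model's calibration
#' anchors (posterior, normalized); posteriors outside the anchor range clamp
#' to the terminal anchor values.
#'
#' @param model an \code{oligo_count_model} with a calibration table.
#' @param posterior numeric vector of posteriors in \[0, 1\].
#' @return numeric vector of normalized scores in \[0, 1\].
#' @export
normalize_score <- function(model, posterior) {
  stopifnot(inherits(model, "oligo_count_model"))
  cal <- model$calibration
  if (is.null(cal) || nrow(cal) == 0L) {
    stop("model has no calibration anchors", call. = FALSE)
  }
  stopifnot(all(posterior >= 0 & posterior <= 1))
  if (nrow(cal) == 1L) return(rep(cal$normalized, length(posterior)))
  stats::approx(cal$posterior, cal$normalized, xout = posterior,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Quantile boundaries for discrete site strength
#'
#' Computes the n_bins-1 equal-probability quantile boundaries of a
#' normalized-score distribution (type-1 quantiles, deterministic).
#'
#' @param scores normalized scores of the reference (true-site) population.
#' @param n_bins number of strength bins (default 5).
#' @return numeric vector of n_bins - 1 non-decreasing break points.
#' @export
strength_breaks <- function(scores, n_bins = 5L) {
  stopifnot(length(scores) > 0L, n_bins >= 2L)
  stats::quantile(scores, probs = seq_len(n_bins - 1L) / n_bins,
                  names = FALSE, type = 1)
}

#' Discretize a normalized score into a 1..n_bins strength class
#'
#' Equal-probability binning of the normalized score against break points
#' derived from the true-site score distribution (see
#' \code{\link{strength_breaks}}).
#'
#' @param normalized_score numeric vector in \[0, 1\].
#' @param breaks break points (ascending); typically
#'   \code{model$strength_breaks}.
#' @return integer vector of strengths in 1..(length(breaks) + 1).
#' @export
discretize_strength <- function(normalized_score, breaks) {
  if (any(normalized_score < 0 | normalized_score > 1)) {
    stop("normalized score outside [0,1]", call. = FALSE)
  }
  stopifnot(length(breaks) >= 1L, !is.unsorted(breaks))
  findInterval(normalized_score, breaks, left.open = TRUE) + 1L
}

#' Scan a sequence for putative splice sites
#'
#' Applies one or more sensors along the forward strand. Donor sensors fire
#' at every GT (or GC) dinucleotide opening a putative intron; the acceptor
#' sensor at every AG closing one. Windows running off the sequence or
#' covering an N are skipped. Positions are 0-based: the first intronic
#' nucleotide for donors, the first exonic nucleotide after the intron for
#' acceptors.
#'
#' @param seq a single DNA sequence (character or \code{DNAString}).
#' @param models named list of \code{oligo_count_model}s (names are ignored;
#'   kinds are read from the models).
#' @param min_posterior minimum posterior to report (default 0).
#' @return data.frame with columns position, kind, oligo, posterior,
#'   normalized_score, strength, lod, sorted by position.
#' @export
scan_splice_sites <- function(seq, models, min_posterior = 0) {
  seq <- as_seq_string(seq)
  check_dna(seq, "sequence")
  if (inherits(models, "oligo_count_model")) models <- list(models)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- lapply(models, function(model) {
    up <- as.integer(model$window[["upstream_nt"]])
    dn <- as.integer(model$window[["downstream_nt"]])
    k <- up + dn
    if (n < k) return(NULL)
    anc <- sensor_anchor(model$sensor_kind)
    a1 <- substr(anc, 1, 1); a2 <- substr(anc, 2, 2)
    idx <- which(chars == a1)
    idx <- idx[idx < n & chars[idx + 1L] == a2]
    if (model$sensor_kind == "acceptor") {
      # AG at 1-based idx..idx+1; site position (first exonic nt, 0-based)
      # is idx + 1; oligo spans [pos - up, pos + dn) 0-based.
      pos0 <- idx + 1L
    } else {
      # GT/GC at idx..idx+1; first intronic nt (0-based) is idx - 1.
      pos0 <- idx - 1L
    }
    start1 <- pos0 - up + 1L  # 1-based oligo start
    keep <- start1 >= 1L & (start1 + k - 1L) <= n
    pos0 <- pos0[keep]; start1 <- start1[keep]
    if (!length(pos0)) return(NULL)
    oligos <- substring(seq, start1, start1 + k - 1L)
    ok <- !grepl("N", oligos, fixed = TRUE)
    pos0 <- pos0[ok]; oligos <- oligos[ok]
    if (!length(pos0)) return(NULL)
    p <- site_posterior(model, oligos)
    keep <- p >= min_posterior
    if (!any(keep)) return(NULL)
    p <- p[keep]; pos0 <- pos0[keep]; oligos <- oligos[keep]
    ns <- normalize_score(model, p)
    data.frame(position = pos0, kind = model$sensor_kind, oligo = oligos,
               posterior = p, normalized_score = ns,
               strength = discretize_strength(ns, model$strength_breaks),
               lod = lod2(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(position = integer(0), kind = character(0),
                      oligo = character(0), posterior = numeric(0),
                      normalized_score = numeric(0), strength = integer(0),
                      lod = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$position, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The packaged non-canonical 5'GC donor count table
#'
#' Returns the bundled 40-row count table behind the GC-donor sensor: each
#' 9-mer (3 exonic + 6 intronic nt, GC at the intron start) with its
#' true-site count, decoy count, published posterior and normalized score.
#' Attributes \code{n_annotated_gc} (1320) and \code{n_confirmed_gc} (19059)
#' carry the training-corpus totals the decoy amplification factor derives
#' from.
#'
#' @return data.frame with columns oligo, true_count, decoy_count, posterior,
#'   normalized.
#' @export
gc_donor_count_table <- function() {
  path <- system.file("extdata", "gc_donor_true_decoy_counts.tsv",
                      package = "splicedef", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(tab, "n_annotated_gc") <- 1320L
  attr(tab, "n_confirmed_gc") <- 19059L
  tab
}

#' Build the GC-donor sensor from the packaged count table
#'
#' Constructs an \code{oligo_count_model} whose counts, calibration anchors
#' and strength breaks all come from the packaged GC-donor table. The
#' calibration interpolates (posterior, normalized) anchor pairs using the
#' exact posteriors t/(t+d) recomputed from the counts, so the published
#' normalized scores are reproduced exactly at the anchors.
#'
#' @param n_bins number of strength bins (default 5).
#' @return an \code{oligo_count_model} of kind \code{donor_GC}.
#' @export
gc_donor_model <- function(n_bins = 5L) {
  tab <- gc_donor_count_table()
  model <- new_oligo_count_model(
    "donor_GC", default_window("donor_GC"),
    true_counts = stats::setNames(as.numeric(tab$true_count), tab$oligo),
    decoy_counts = stats::setNames(as.numeric(tab$decoy_count), tab$oligo),
    amplification_factor =
      attr(tab, "n_confirmed_gc") / attr(tab, "n_annotated_gc"))
  p_exact <- site_posterior(model, tab$oligo)
  ord <- order(p_exact)
  model$calibration <- data.frame(posterior = p_exact[ord],
                                  normalized = tab$normalized[ord])
  norm_true <- normalize_score(model, p_exact)
  model$strength_breaks <- strength_breaks(rep(norm_true, tab$true_count),
                                           n_bins = n_bins)
  validate_oligo_count_model(model)
}
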