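# Model bundle: the trained sensors, element profiles, length model and
# exon-score calibration travelling together, with lossless directory
# serialization.

BUNDLE_VERSION <- "splicedef-bundle-1"

#' Train a full splicing model from a synthetic (or user-assembled) corpus
#'
#' Trains the three sensors from the corpus site oligos (decoys harvested
#' from the introns), builds intronic-enhancer LOD profiles from the donor
#' flank contexts, fits the strength-conditioned exon-length model using the
#' sensors' own strength calls at the true sites, and records the empirical
#' distribution of true-exon total LODs as the exon-score calibration
#' (GC-donor exons keep a separate distribution when present).
#'
#' @param corpus a \code{synthetic_corpus} (or any list with the same
#'   fields).
#' @param element_motifs motif table (motif, element_class, side); defaults
#'   to the intronic enhancers of \code{\link{demo_element_motifs}}.
#' @param k length-mixture components per cell (default 2).
#' @param n_bins strength classes (default 5).
#' @param sensor_pseudocount pseudocount handed to the sensors (default 0).
#' @param smoothing_window,profile_pseudocount LOD-profile knobs
#'   (defaults 11 and 0.5).
#' @param competitor_scale competitor penalty scale recorded in the bundle
#'   parameters (default 0.5).
#' @return object of class \code{splice_model}.
#' @export
train_splice_model <- function(corpus,
                               element_motifs = NULL,
                               k = 2L, n_bins = 5L,
                               sensor_pseudocount = 0,
                               smoothing_window = 11L,
                               profile_pseudocount = 0.5,
                               competitor_scale = 0.5) {
  truth <- corpus$truth
  sensors <- list()
  gt_idx <- corpus$true_donor_kinds == "donor_GT"
  sensors$donor_GT <- train_oligo_model(
    corpus$true_donor_oligos[gt_idx],
    harvest_decoy_oligos(corpus, "donor_GT"),
    "donor_GT", pseudocount = sensor_pseudocount, n_bins = n_bins)
  if (any(!gt_idx)) {
    sensors$donor_GC <- train_oligo_model(
      corpus$true_donor_oligos[!gt_idx],
      harvest_decoy_oligos(corpus, "donor_GC"),
      "donor_GC", pseudocount = sensor_pseudocount, n_bins = n_bins)
  }
  sensors$acceptor <- train_oligo_model(
    corpus$true_acceptor_oligos,
    harvest_decoy_oligos(corpus, "acceptor"),
    "acceptor", pseudocount = sensor_pseudocount, n_bins = n_bins)

  if (is.null(element_motifs)) {
    em <- demo_element_motifs()
    element_motifs <- em[em$element_class == "ISE", , drop = FALSE]
  }
  profiles <- list()
  if (!is.null(element_motifs) && nrow(element_motifs) &&
      length(corpus$true_donor_flanks) && length(corpus$decoy_donor_flanks)) {
    profiles <- lapply(seq_len(nrow(element_motifs)), function(i) {
      build_lod_profile(element_motifs$motif[i],
                        element_motifs$element_class[i],
                        element_motifs$side[i],
                        corpus$true_donor_flanks,
                        corpus$decoy_donor_flanks,
                        ss_column = 1L,
                        smoothing_window = smoothing_window,
                        pseudocount = profile_pseudocount)
    })
  }

  # Sensor-called strengths at the true sites condition the length model.
  s3 <- site_strength(sensors$acceptor, corpus$true_acceptor_oligos)
  s5 <- integer(nrow(truth))
  s5[gt_idx] <- site_strength(sensors$donor_GT,
                              corpus$true_donor_oligos[gt_idx])
  if (any(!gt_idx)) {
    s5[!gt_idx] <- site_strength(sensors$donor_GC,
                                 corpus$true_donor_oligos[!gt_idx])
  }
  max_len <- corpus$spec$max_len %||% 400L
  length_model <- tryCatch(
    fit_length_model(truth$length, s3, s5, k = k, max_len = max_len,
                     n_bins = n_bins),
    error = function(e) tryCatch(
      fit_length_model(truth$length, s3, s5, k = 1L, max_len = max_len,
                       n_bins = n_bins),
      error = function(e2) {
        warning("too few exons to fit a length model; using the uniform law")
        uniform_length_model(max_len = max_len, n_bins = n_bins)
      }))

  # Exon-score calibration: total LOD of every true exon (sensor terms,
  # length term, intronic element term; no competitor term at train time).
  p3 <- site_posterior(sensors$acceptor, corpus$true_acceptor_oligos)
  p5 <- numeric(nrow(truth))
  p5[gt_idx] <- site_posterior(sensors$donor_GT,
                               corpus$true_donor_oligos[gt_idx])
  if (any(!gt_idx)) {
    p5[!gt_idx] <- site_posterior(sensors$donor_GC,
                                  corpus$true_donor_oligos[!gt_idx])
  }
  elem <- vapply(seq_len(nrow(truth)), function(i) {
    fl <- corpus$true_donor_flanks[i]
    hits <- scan_elements(fl, c(0L, nchar(fl)), profiles,
                          anchor_position = 0L)
    element_lod_sum(resolve_overlaps(hits))
  }, numeric(1))
  total <- lod2(p3) + lod2(p5) +
    length_lod_vec(length_model, s3, s5, truth$length) + elem
  exon_calibration <- list(default = sort(total[gt_idx]))
  if (any(!gt_idx)) exon_calibration$donor_GC <- sort(total[!gt_idx])
  if (!length(exon_calibration$default)) {
    exon_calibration$default <- sort(total)
  }

  structure(list(sensors = sensors, profiles = profiles,
                 length_model = length_model,
                 exon_calibration = exon_calibration,
                 version = BUNDLE_VERSION,
                 parameters = list(k = k, n_bins = n_bins,
                                   sensor_pseudocount = sensor_pseudocount,
                                   smoothing_window = smoothing_window,
                                   profile_pseudocount = profile_pseudocount,
                                   competitor_scale = competitor_scale)),
            class = "splice_model")
}

site_strength <- function(model, oligos) {
  p <- site_posterior(model, oligos)
  discretize_strength(normalize_score(model, p), model$strength_breaks)
}

length_lod_vec <- function(model, s3, s5, size) {
  vapply(seq_along(size), function(i) {
    length_lod(model, s3[i], s5[i], size[i])
  }, numeric(1))
}

#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf("splice model bundle (%s)\n", x$version))
  cat("  sensors:", paste(names(x$sensors), collapse = ", "), "\n")
  cat(sprintf("  element profiles: %d; length model: %s\n",
              length(x$profiles),
              if (is.null(x$length_model)) "none" else "fitted"))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Save a model bundle to a directory
#'
#' Writes a YAML manifest plus one TSV per component (sensor count tables
#' and calibrations, element profiles, length-model parameters, exon-score
#' calibration). Numbers are written with 17 significant digits so that a
#' load/save cycle is lossless.
#'
#' @param bundle a \code{splice_model}.
#' @param path directory to create/overwrite.
#' @return the path, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "splice_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(version = bundle$version,
               parameters = bundle$parameters,
               sensors = lapply(bundle$sensors, function(m) {
                 list(sensor_kind = m$sensor_kind,
                      upstream_nt = unname(m$window[[1]]),
                      downstream_nt = unname(m$window[[2]]),
                      amplification_factor = fmt_num(m$amplification_factor),
                      pseudocount = fmt_num(m$pseudocount),
                      strength_breaks = fmt_num(m$strength_breaks))
               }),
               profiles = lapply(bundle$profiles, function(pr) {
                 list(motif = pr$motif, element_class = pr$element_class,
                      side = pr$side,
                      strength_class = as.integer(pr$strength_class),
                      n_true = pr$n_true, n_decoy = pr$n_decoy,
                      smoothing_window = pr$smoothing_window,
                      pseudocount = fmt_num(pr$pseudocount))
               }),
               length_model = if (is.null(bundle$length_model)) NULL else
                 list(n_bins = bundle$length_model$n_bins,
                      max_len = bundle$length_model$max_len,
                      k = bundle$length_model$k))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  for (kind in names(bundle$sensors)) {
    m <- bundle$sensors[[kind]]
    all_oligos <- sort(union(names(m$true_counts), names(m$decoy_counts)))
    tc <- m$true_counts[all_oligos]; tc[is.na(tc)] <- 0
    dc <- m$decoy_counts[all_oligos]; dc[is.na(dc)] <- 0
    utils::write.table(
      data.frame(oligo = all_oligos, true_count = fmt_num(tc),
                 decoy_count = fmt_num(dc)),
      file.path(path, paste0("sensor_", kind, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(posterior = fmt_num(m$calibration$posterior),
                 normalized = fmt_num(m$calibration$normalized)),
      file.path(path, paste0("sensor_", kind, "_calibration.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(bundle$profiles)) {
    prof <- do.call(rbind, lapply(seq_along(bundle$profiles), function(i) {
      pr <- bundle$profiles[[i]]
      data.frame(profile = i, offset = pr$offsets, lod = fmt_num(pr$lod),
                 support_true = pr$support_true,
                 support_decoy = pr$support_decoy)
    }))
    utils::write.table(prof, file.path(path, "profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$length_model)) {
    lm <- bundle$length_model
    rows <- do.call(rbind, lapply(seq_len(nrow(lm$cells)), function(i) {
      mix <- lm$grid[[i]]
      data.frame(s3 = lm$cells$s3[i], s5 = lm$cells$s5[i],
                 component = seq_len(mix$k),
                 weight = fmt_num(mix$weights), alpha = fmt_num(mix$alphas),
                 beta = fmt_num(mix$betas),
                 n_cell = lm$counts[lm$cells$s3[i], lm$cells$s5[i]])
    }))
    utils::write.table(rows, file.path(path, "length_model.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$exon_calibration)) {
    rows <- do.call(rbind, lapply(names(bundle$exon_calibration), function(nm) {
      data.frame(set = nm, total_lod = fmt_num(bundle$exon_calibration[[nm]]))
    }))
    utils::write.table(rows, file.path(path, "exon_calibration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load a model bundle from a directory
#'
#' @param path directory written by \code{\link{save_bundle}}.
#' @return a \code{splice_model}.
#' @export
load_bundle <- function(path) {
  meta_path <- file.path(path, "meta.yaml")
  if (!file.exists(meta_path)) {
    stop("not a model bundle: missing meta.yaml in ", path, call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  if (!identical(meta$version, BUNDLE_VERSION)) {
    stop(sprintf("bundle version mismatch: found %s, this build reads %s",
                 meta$version %||% "<none>", BUNDLE_VERSION), call. = FALSE)
  }
  if (is.null(meta$sensors) || !length(meta$sensors)) {
    stop("partial bundle: no sensors recorded in manifest", call. = FALSE)
  }
  sensors <- list()
  for (kind in names(meta$sensors)) {
    sm <- meta$sensors[[kind]]
    counts_path <- file.path(path, paste0("sensor_", kind, ".tsv"))
    cal_path <- file.path(path, paste0("sensor_", kind, "_calibration.tsv"))
    if (!file.exists(counts_path) || !file.exists(cal_path)) {
      stop("partial bundle: missing files for sensor ", kind, call. = FALSE)
    }
    tab <- utils::read.delim(counts_path, stringsAsFactors = FALSE)
    cal <- utils::read.delim(cal_path, stringsAsFactors = FALSE)
    tc <- stats::setNames(as.numeric(tab$true_count), tab$oligo)
    dc <- stats::setNames(as.numeric(tab$decoy_count), tab$oligo)
    m <- new_oligo_count_model(
      sm$sensor_kind,
      c(upstream_nt = as.integer(sm$upstream_nt),
        downstream_nt = as.integer(sm$downstream_nt)),
      true_counts = tc[tc > 0], decoy_counts = dc[dc > 0],
      amplification_factor = as.numeric(sm$amplification_factor),
      calibration = data.frame(posterior = as.numeric(cal$posterior),
                               normalized = as.numeric(cal$normalized)),
      strength_breaks = as.numeric(sm$strength_breaks),
      pseudocount = as.numeric(sm$pseudocount))
    sensors[[kind]] <- m
  }
  profiles <- list()
  if (length(meta$profiles)) {
    prof_path <- file.path(path, "profiles.tsv")
    if (!file.exists(prof_path)) {
      stop("partial bundle: manifest lists profiles but profiles.tsv is absent",
           call. = FALSE)
    }
    tab <- utils::read.delim(prof_path, stringsAsFactors = FALSE)
    profiles <- lapply(seq_along(meta$profiles), function(i) {
      pm <- meta$profiles[[i]]
      rows <- tab[tab$profile == i, , drop = FALSE]
      structure(list(motif = pm$motif, element_class = pm$element_class,
                     side = pm$side,
                     strength_class = pm$strength_class %||% NA_integer_,
                     offsets = as.integer(rows$offset),
                     lod = as.numeric(rows$lod),
                     support_true = as.numeric(rows$support_true),
                     support_decoy = as.numeric(rows$support_decoy),
                     n_true = pm$n_true, n_decoy = pm$n_decoy,
                     smoothing_window = pm$smoothing_window,
                     pseudocount = as.numeric(pm$pseudocount)),
                class = "cis_element_profile")
    })
  }
  length_model <- NULL
  if (!is.null(meta$length_model)) {
    lm_path <- file.path(path, "length_model.tsv")
    if (!file.exists(lm_path)) {
      stop("partial bundle: manifest lists a length model but length_model.tsv is absent",
           call. = FALSE)
    }
    tab <- utils::read.delim(lm_path, stringsAsFactors = FALSE)
    n_bins <- as.integer(meta$length_model$n_bins)
    cells <- expand.grid(s3 = seq_len(n_bins), s5 = seq_len(n_bins))
    counts <- matrix(0L, n_bins, n_bins)
    grid <- lapply(seq_len(nrow(cells)), function(i) {
      rows <- tab[tab$s3 == cells$s3[i] & tab$s5 == cells$s5[i], ,
                  drop = FALSE]
      counts[cells$s3[i], cells$s5[i]] <<- rows$n_cell[1]
      structure(list(k = nrow(rows), weights = as.numeric(rows$weight),
                     alphas = as.numeric(rows$alpha),
                     betas = as.numeric(rows$beta),
                     loglik = NA_real_, loglik_trace = NULL,
                     n_iter = NA_integer_, n_obs = NA_integer_),
                class = "beta_mixture")
    })
    length_model <- structure(
      list(grid = grid, cells = cells, counts = counts, n_bins = n_bins,
           max_len = as.integer(meta$length_model$max_len),
           k = as.integer(meta$length_model$k), pooled = NULL),
      class = "length_model")
  }
  exon_calibration <- NULL
  cal_path <- file.path(path, "exon_calibration.tsv")
  if (file.exists(cal_path)) {
    tab <- utils::read.delim(cal_path, stringsAsFactors = FALSE)
    exon_calibration <- lapply(split(tab$total_lod, tab$set), as.numeric)
  }
  structure(list(sensors = sensors, profiles = profiles,
                 length_model = length_model,
                 exon_calibration = exon_calibration,
                 version = meta$version, parameters = meta$parameters),
            class = "splice_model")
}

#' Predict the splicing effect of one variant
#'
#' Convenience wrapper: validates and applies the variant, scans the
#' reference and alternate sequences under the same parameter snapshot, and
#' classifies the differences.
#'
#' @param seq reference sequence.
#' @param variant a \code{variant_spec} or IVS string (resolved against the
#'   annotation).
#' @param model a \code{splice_model} bundle.
#' @param annotation annotated exon data.frame (1-based start/end).
#' @param score_change_threshold relative score-change cutoff (default
#'   0.02).
#' @param ... passed to \code{\link{scan_sequence}}.
#' @return list with \code{ref_scan}, \code{alt_scan}, \code{map},
#'   \code{events}.
#' @export
variant_effects <- function(seq, variant, model, annotation = NULL,
                            score_change_threshold = 0.02, ...) {
  if (is.character(variant)) {
    variant <- parse_ivs_variant(variant, annotation, seq = seq)
  }
  seq <- as_seq_string(seq)
  app <- apply_variant(seq, variant)
  ref_scan <- scan_sequence(seq, model, sequence_id = "ref", ...)
  alt_scan <- scan_sequence(app$alt_seq, model, sequence_id = "alt", ...)
  events <- classify_events(ref_scan, alt_scan, app, annotation,
                            score_change_threshold = score_change_threshold)
  list(ref_scan = ref_scan, alt_scan = alt_scan, map = app, events = events)
}
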