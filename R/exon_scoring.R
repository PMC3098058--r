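# Strength-conditioned exon-length model and the combined exon-definition
# LOD score.
#
# Internal exon lengths, scaled to (0,1) by max_len, are modeled per
# (acceptor strength, donor strength) cell as a mixture of Beta densities
# fit by EM. The length term of the exon score is the log2 ratio of the
# mixture density to the uniform reference density (1 on the scaled
# support), so pseudoexon lengths are the null.

#' Fit a Beta mixture to (0,1) data by expectation maximization
#'
#' Initialization is method-of-moments on k quantile slices of the sorted
#' data. The M-step maximizes each component's weighted Beta log-likelihood
#' numerically (L-BFGS-B on log-parameters); a guard keeps the previous
#' parameters whenever the optimizer fails to improve the weighted
#' likelihood, so the observed log-likelihood is non-decreasing across
#' iterations. Components whose weight collapses below 1e-6 are pruned with
#' a warning.
#'
#' @param x numeric data strictly inside (0, 1).
#' @param k number of mixture components.
#' @param tol relative log-likelihood improvement at which to stop.
#' @param max_iter iteration cap.
#' @return object of class \code{beta_mixture}: k, weights, alphas, betas,
#'   loglik, loglik_trace, n_iter, n_obs.
#' @examples
#' set.seed(1)
#' fit <- fit_beta_mixture(rbeta(500, 2, 5), k = 1)
#' @export
fit_beta_mixture <- function(x, k = 2L, tol = 1e-6, max_iter = 500L) {
  stopifnot(k >= 1L)
  x <- as.numeric(x)
  if (any(x <= 0 | x >= 1)) stop("data must lie strictly in (0,1)", call. = FALSE)
  if (length(x) < 10L * k) {
    stop("insufficient data: need at least 10 observations per component",
         call. = FALSE)
  }
  if (stats::var(x) < 1e-12) {
    stop("degenerate input: observations are (nearly) identical", call. = FALSE)
  }
  # Method-of-moments initialization on quantile slices.
  xs <- sort(x)
  slice <- if (k == 1L) rep(1L, length(xs)) else {
    cut(seq_along(xs), breaks = k, labels = FALSE)
  }
  pars <- t(vapply(seq_len(k), function(j) {
    moments_beta(xs[slice == j])
  }, numeric(2)))
  weights <- rep(1 / k, k)
  alphas <- pars[, 1]; betas <- pars[, 2]

  ll_trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    dens <- vapply(seq_len(k), function(j) {
      weights[j] * stats::dbeta(x, alphas[j], betas[j])
    }, numeric(length(x)))
    dens <- matrix(dens, nrow = length(x))
    rs <- rowSums(dens)
    rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(rs))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rs
    # M-step
    weights <- colMeans(resp)
    for (j in seq_len(k)) {
      fit <- weighted_beta_mle(x, resp[, j], alphas[j], betas[j])
      alphas[j] <- fit[1]; betas[j] <- fit[2]
    }
    if (is.finite(ll_old) &&
        (ll - ll_old) < tol * max(1, abs(ll_old))) break
    if (it >= max_iter) break
    ll_old <- ll
  }
  drop <- weights < 1e-6
  if (any(drop)) {
    warning("pruning ", sum(drop), " degenerate mixture component(s)")
    weights <- weights[!drop] / sum(weights[!drop])
    alphas <- alphas[!drop]; betas <- betas[!drop]
    k <- length(weights)
  }
  structure(list(k = k, weights = weights, alphas = alphas, betas = betas,
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n_iter = it, n_obs = length(x)),
            class = "beta_mixture")
}

moments_beta <- function(x) {
  m <- mean(x); v <- stats::var(x)
  v <- max(v, 1e-8)
  if (v >= m * (1 - m)) v <- 0.9 * m * (1 - m)
  common <- m * (1 - m) / v - 1
  c(max(m * common, 0.05), max((1 - m) * common, 0.05))
}

# Weighted Beta MLE; never returns parameters with a worse weighted
# log-likelihood than the starting point.
weighted_beta_mle <- function(x, w, alpha0, beta0) {
  sw <- sum(w)
  if (sw < 1e-12) return(c(alpha0, beta0))
  nll <- function(theta) {
    -sum(w * stats::dbeta(x, exp(theta[1]), exp(theta[2]), log = TRUE))
  }
  start <- log(c(alpha0, beta0))
  opt <- tryCatch(
    stats::optim(start, nll, method = "L-BFGS-B",
                 lower = log(1e-3), upper = log(1e4)),
    error = function(e) NULL)
  if (is.null(opt) || opt$value > nll(start)) return(c(alpha0, beta0))
  exp(opt$par)
}

#' Beta-mixture density
#'
#' @param x numeric vector in (0,1).
#' @param mixture a \code{beta_mixture}.
#' @return mixture density values.
#' @export
dbeta_mixture <- function(x, mixture) {
  stopifnot(inherits(mixture, "beta_mixture"))
  out <- numeric(length(x))
  for (j in seq_len(mixture$k)) {
    out <- out + mixture$weights[j] *
      stats::dbeta(x, mixture$alphas[j], mixture$betas[j])
  }
  out
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat(sprintf("Beta mixture (k = %d, n = %d, loglik = %.2f)\n",
              x$k, x$n_obs, x$loglik))
  for (j in seq_len(x$k)) {
    cat(sprintf("  w = %.3f  Beta(%.3f, %.3f)\n",
                x$weights[j], x$alphas[j], x$betas[j]))
  }
  invisible(x)
}

#' Fit the strength-conditioned exon-length model
#'
#' Fits one Beta mixture per (acceptor strength, donor strength) cell of the
#' n_bins x n_bins grid. Cells with fewer than \code{min_cell} observations
#' borrow the fit of the Manhattan-nearest populated cell (ties: the cell
#' with more observations, then row-major order); if no cell is populated the
#' pooled fit over all lengths is used.
#'
#' @param lengths exon lengths in nt, each in (0, max_len).
#' @param s3,s5 acceptor / donor strength classes (1..n_bins) per exon.
#' @param k mixture components per cell (default 2).
#' @param max_len length scale in nt (default 400).
#' @param n_bins strength classes per axis (default 5).
#' @param min_cell minimum observations to fit a cell directly (default 50).
#' @param ... passed to \code{\link{fit_beta_mixture}}.
#' @return object of class \code{length_model}.
#' @export
fit_length_model <- function(lengths, s3, s5, k = 2L, max_len = 400L,
                             n_bins = 5L, min_cell = 50L, ...) {
  stopifnot(length(lengths) == length(s3), length(s3) == length(s5))
  if (any(lengths <= 0 | lengths >= max_len)) {
    stop("lengths must lie strictly in (0, max_len)", call. = FALSE)
  }
  x <- lengths / max_len
  pooled <- fit_beta_mixture(x, k = k, ...)
  cells <- expand.grid(s3 = seq_len(n_bins), s5 = seq_len(n_bins))
  counts <- matrix(0L, n_bins, n_bins)
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- s3 == cells$s3[i] & s5 == cells$s5[i]
    counts[cells$s3[i], cells$s5[i]] <- sum(sel)
    if (sum(sel) >= max(min_cell, 10L * k)) {
      fits[[i]] <- tryCatch(fit_beta_mixture(x[sel], k = k, ...),
                            error = function(e) NULL)
    }
  }
  populated <- which(!vapply(fits, is.null, logical(1)))
  for (i in seq_len(nrow(cells))) {
    if (!is.null(fits[[i]])) next
    if (!length(populated)) { fits[[i]] <- pooled; next }
    dist <- abs(cells$s3[populated] - cells$s3[i]) +
      abs(cells$s5[populated] - cells$s5[i])
    nbr <- populated[order(dist,
                           -counts[cbind(cells$s3[populated],
                                         cells$s5[populated])],
                           populated)][1]
    fits[[i]] <- fits[[nbr]]
  }
  structure(list(grid = fits, cells = cells, counts = counts,
                 n_bins = n_bins, max_len = max_len, k = k,
                 pooled = pooled),
            class = "length_model")
}

length_model_cell <- function(model, s3, s5) {
  i <- which(model$cells$s3 == s3 & model$cells$s5 == s5)
  if (!length(i)) stop("strength class outside the model grid", call. = FALSE)
  model$grid[[i]]
}

#' @export
print.length_model <- function(x, ...) {
  cat(sprintf("Exon-length model: %dx%d strength grid, k = %d, max_len = %d nt\n",
              x$n_bins, x$n_bins, x$k, x$max_len))
  cat("  observations per cell (rows: acceptor strength):\n")
  print(x$counts)
  invisible(x)
}

#' Length LOD of an exon given its flanking site strengths
#'
#' log2 of the fitted mixture density at size/max_len against the uniform
#' reference density 1 on the scaled support.
#'
#' @param model a \code{length_model}.
#' @param s3 acceptor strength class.
#' @param s5 donor strength class.
#' @param size exon length in nt, in (0, max_len).
#' @return LOD in bits.
#' @export
length_lod <- function(model, s3, s5, size) {
  stopifnot(inherits(model, "length_model"))
  if (any(size <= 0 | size >= model$max_len)) {
    stop("size must lie strictly in (0, max_len)", call. = FALSE)
  }
  mix <- length_model_cell(model, s3, s5)
  dens <- dbeta_mixture(size / model$max_len, mix)
  dens <- pmax(dens, 2^(-LOD_CLAMP))
  pmin(log2(dens), LOD_CLAMP)
}

#' A uniform (neutral) length model
#'
#' Single-component Beta(1,1) in every cell; its length LOD is identically
#' zero. Useful as a null model and in tests.
#'
#' @param max_len length scale in nt.
#' @param n_bins strength classes per axis.
#' @return a \code{length_model}.
#' @export
uniform_length_model <- function(max_len = 400L, n_bins = 5L) {
  mix <- structure(list(k = 1L, weights = 1, alphas = 1, betas = 1,
                        loglik = 0, loglik_trace = 0, n_iter = 0L,
                        n_obs = 0L), class = "beta_mixture")
  cells <- expand.grid(s3 = seq_len(n_bins), s5 = seq_len(n_bins))
  structure(list(grid = rep(list(mix), nrow(cells)), cells = cells,
                 counts = matrix(0L, n_bins, n_bins), n_bins = n_bins,
                 max_len = max_len, k = 1L, pooled = mix),
            class = "length_model")
}

#' Combine the five evidence terms into an exon-definition score
#'
#' The candidate exon's total LOD is the exact sum of five components: the
#' acceptor and donor sensor LODs (log2 odds of their posteriors), the
#' length LOD under the strength-conditioned length model, the summed LOD of
#' the overlap-resolved cis-element hits, and a negative competitor term
#' (minus \code{competitor_scale} times the summed positive LOD of strong
#' competing same-side sites near or inside the exon). The normalized score
#' is the total LOD's percentile under the supplied calibration (the
#' empirical distribution of total LODs over true exons; GC-donor exons use
#' their own calibration), or a logistic squash when no calibration is
#' given.
#'
#' @param acceptor,donor single splice-site call rows (as produced by
#'   \code{\link{scan_splice_sites}}); the donor must lie downstream.
#' @param element_hits overlap-resolved element hits for this exon.
#' @param competitor_hits site calls acting as competitors (same-side strong
#'   sites near or inside the exon, excluding the exon's own sites).
#' @param length_model a \code{length_model} or NULL (length term 0).
#' @param exon_calibration optional sorted numeric vector of reference total
#'   LODs (see \code{\link{train_splice_model}}).
#' @param competitor_scale multiplier on the competitor penalty (default 0.5).
#' @param min_len,max_len admissible exon length bounds (default 6..399 nt).
#' @return object of class \code{candidate_exon}.
#' @export
score_exon <- function(acceptor, donor, element_hits = empty_hits(),
                       competitor_hits = NULL, length_model = NULL,
                       exon_calibration = NULL, competitor_scale = 0.5,
                       min_len = 6L, max_len = 399L) {
  if (donor$position <= acceptor$position) {
    stop("donor must lie downstream of the acceptor", call. = FALSE)
  }
  len <- donor$position - acceptor$position
  if (len < min_len || len > max_len) {
    stop(sprintf("exon length %d outside (%d, %d)", len,
                 min_len - 1L, max_len + 1L), call. = FALSE)
  }
  lod_acceptor <- lod2(acceptor$posterior)
  lod_donor <- lod2(donor$posterior)
  lod_length <- if (is.null(length_model)) 0 else {
    length_lod(length_model, acceptor$strength, donor$strength, len)
  }
  lod_elements <- element_lod_sum(element_hits)
  lod_competitors <- if (is.null(competitor_hits) || nrow(competitor_hits) == 0L) 0 else {
    -competitor_scale * sum(pmax(competitor_hits$lod, 0))
  }
  total <- lod_acceptor + lod_donor + lod_length + lod_elements +
    lod_competitors
  norm <- normalize_exon_score(total, donor$kind, exon_calibration)
  structure(list(acceptor = acceptor, donor = donor, length = len,
                 lod_acceptor = lod_acceptor, lod_donor = lod_donor,
                 lod_length = lod_length, lod_elements = lod_elements,
                 lod_competitors = lod_competitors, total_lod = total,
                 normalized_exon_score = norm,
                 element_hits = element_hits,
                 competitor_hits = competitor_hits),
            class = "candidate_exon")
}

# Percentile of a total LOD under the reference distribution; GC-donor
# exons carry their own normalization histogram. Fallback: base-2 logistic.
normalize_exon_score <- function(total_lod, donor_kind, exon_calibration) {
  ref <- NULL
  if (!is.null(exon_calibration)) {
    if (is.list(exon_calibration) && !is.null(exon_calibration[[1]])) {
      ref <- if (identical(donor_kind, "donor_GC") &&
                 !is.null(exon_calibration$donor_GC)) {
        exon_calibration$donor_GC
      } else {
        exon_calibration$default
      }
    } else if (is.numeric(exon_calibration)) {
      ref <- exon_calibration
    }
  }
  if (is.null(ref) || !length(ref)) return(1 / (1 + 2^(-total_lod)))
  (findInterval(total_lod, sort(ref)) + 0.5) / (length(ref) + 1)
}

#' @export
print.candidate_exon <- function(x, ...) {
  cat(report_factors(x))
  invisible(x)
}
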