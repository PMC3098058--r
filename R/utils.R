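# Shared helpers: LOD arithmetic, sequence checks, small validators.

# Largest |LOD| reported for degenerate posteriors 0/1 (log2 odds of 1e-9).
LOD_CLAMP <- 30

#' Log2 odds of a posterior probability
#'
#' Converts a posterior probability into a log2 odds (LOD) value,
#' clamping at +/-30 bits for posteriors of exactly 0 or 1.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return numeric vector of LOD values in \[-30, 30\].
#' @export
lod2 <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  out <- log2(p / (1 - p))
  pmin(pmax(out, -LOD_CLAMP), LOD_CLAMP)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (count tables are integral).
round_half_up <- function(x) floor(x + 0.5)

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside ACGTN: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Single sequence as an uppercase character scalar (accepts DNAString too).
as_seq_string <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "XString")) {
    seq <- as.character(seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  toupper(seq)
}

# 0-based half-open interval overlap test.
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
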