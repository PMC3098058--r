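# Shared fixture builders: tiny sensors, element hits, the exhaustive
# overlap-resolution oracle, and cached expensive corpora.

make_call <- function(position, kind = "donor_GT", posterior = 0.5,
                      strength = 3L, oligo = NA_character_) {
  data.frame(position = position, kind = kind, oligo = oligo,
             posterior = posterior,
             normalized_score = posterior, strength = strength,
             lod = lod2(posterior), stringsAsFactors = FALSE)
}

make_hit <- function(start, lod, width = 7L, motif = "MOTIF",
                     class = if (lod >= 0) "ISE" else "ISS") {
  data.frame(motif = motif, start = start, end = start + width,
             offset = start, lod = lod, element_class = class,
             stringsAsFactors = FALSE)
}

random_hits <- function(n, span = 40L) {
  if (n == 0L) {
    return(make_hit(0L, 1)[0, , drop = FALSE])
  }
  starts <- sample.int(span, n, replace = TRUE)
  widths <- sample(3:9, n, replace = TRUE)
  data.frame(motif = sprintf("m%02d", seq_len(n)), start = starts,
             end = starts + widths, offset = starts,
             lod = stats::runif(n, -2, 2),
             element_class = "ISE", stringsAsFactors = FALSE)
}

# Exhaustive-subset oracle for overlap resolution within one sign class:
# the unique independent set S such that every excluded hit overlaps a
# member of S that precedes it in the (desc |LOD|, start, motif) order.
oracle_resolve_sign <- function(hits) {
  n <- nrow(hits)
  if (n <= 1L) return(hits)
  rank <- order(order(-abs(hits$lod), hits$start, hits$motif))
  ov <- outer(seq_len(n), seq_len(n), function(i, j) {
    hits$start[i] < hits$end[j] & hits$start[j] < hits$end[i]
  })
  diag(ov) <- FALSE
  solutions <- list()
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(S) > 1L && any(ov[S, S])) next
    excl <- setdiff(seq_len(n), S)
    ok <- all(vapply(excl, function(h) {
      any(ov[h, S] & rank[S] < rank[h])
    }, logical(1)))
    if (ok) solutions[[length(solutions) + 1L]] <- S
  }
  stopifnot(length(solutions) == 1L)
  out <- hits[sort(solutions[[1L]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_resolve <- function(hits) {
  pos <- oracle_resolve_sign(hits[hits$lod >= 0, , drop = FALSE])
  neg <- oracle_resolve_sign(hits[hits$lod < 0, , drop = FALSE])
  out <- rbind(pos, neg)
  out <- out[order(out$start, out$end, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sensor whose one oligo has exact counts t and d.
counts_sensor <- function(oligo, t, d, kind = "donor_GT",
                          pseudocount = 0) {
  train_oligo_model(rep(oligo, t), rep(oligo, d), kind,
                    pseudocount = pseudocount)
}

# Minimal fake scan_result for classifier tests.
fake_scan <- function(exons_df) {
  if (is.null(exons_df$reported)) exons_df$reported <- TRUE
  structure(list(sequence_id = "fake", sites = NULL, exons = exons_df,
                 parameters = list()),
            class = "scan_result")
}

fake_exon <- function(acc, don, score = 0.8, kind = "donor_GT") {
  data.frame(acceptor_pos = acc, donor_pos = don, donor_kind = kind,
             length = don - acc, normalized_score = score,
             reported = TRUE, stringsAsFactors = FALSE)
}

identity_map <- function(n) {
  list(ref_to_alt = seq_len(n), alt_to_ref = seq_len(n))
}

# Cached expensive fixtures (built once per test run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_corpus <- function() {
  cached("small_corpus", function() {
    generate_corpus(corpus_spec(seed = 101, n_genes = 25))
  })
}

small_model <- function() {
  cached("small_model", function() train_splice_model(small_corpus()))
}

# Deterministic strong-site corpus/model for variant-effect tests.
variant_model <- function() {
  cached("variant_model", function() {
    spec <- corpus_spec(seed = 202, n_genes = 40, gc_donor_fraction = 0.3,
                        strength_range = 5)
    train_splice_model(generate_corpus(spec))
  })
}
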