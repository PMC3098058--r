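# Format I/O shared by the modules: FASTA sequences, GFF3/BED exon
# annotations, variant tables, event tables.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read an exon annotation from GFF3 or BED
#'
#' Keeps exon-like features (type containing "exon" for GFF3; all BED
#' records) and returns 1-based inclusive coordinates per sequence.
#'
#' @param path annotation file (format inferred from the extension).
#' @return data.frame with columns seq_id, start, end, ordered by start.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type)) {
    keep <- grepl("exon", as.character(gr$type), ignore.case = TRUE)
    if (any(keep)) gr <- gr[keep]
  }
  out <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Write an exon annotation as GFF3
#'
#' @param exons data.frame with seq_id, start, end (1-based inclusive).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotation_gff3 <- function(exons, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$seq_id,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    type = rep("exon", nrow(exons)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a variant table
#'
#' TSV with columns \code{seq_id} plus either absolute coordinates
#' (\code{pos}, \code{ref}, \code{alt}) or an \code{ivs} column with
#' intron-relative notation resolved against the annotation.
#'
#' @param path TSV file.
#' @param annotation per-sequence exon annotation (needed for IVS rows):
#'   data.frame seq_id/start/end.
#' @param seqs named character vector of reference sequences (needed when
#'   IVS deletions/duplications omit the allele).
#' @return named list of \code{variant_spec} objects (one per row), named
#'   by seq_id.
#' @export
read_variant_table <- function(path, annotation = NULL, seqs = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    ivs <- if (is.null(tab$ivs)) NA_character_ else tab$ivs[i]
    if (!is.na(ivs) && nzchar(ivs)) {
      if (is.null(annotation)) {
        stop("IVS variants need an annotation", call. = FALSE)
      }
      ann <- annotation[annotation$seq_id == tab$seq_id[i], , drop = FALSE]
      parse_ivs_variant(ivs, ann,
                        seq = if (is.null(seqs)) NULL else seqs[[tab$seq_id[i]]])
    } else {
      variant_spec(tab$pos[i], tab$ref[i] %||% "", tab$alt[i] %||% "")
    }
  })
  stats::setNames(out, tab$seq_id)
}

#' Write a splicing-event table as TSV
#'
#' @param events event data.frame from \code{\link{classify_events}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Recall of planted exons under a trained model
#'
#' Scans every corpus gene and reports the fraction of planted exons whose
#' exact (acceptor, donor) boundary pair appears among the candidate exons
#' at or above the report threshold.
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param model a \code{splice_model}.
#' @param report_threshold normalized-score threshold (default 0:
#'   permissive).
#' @param ... further arguments to \code{\link{scan_sequence}}.
#' @return list with \code{recall}, \code{n_true}, \code{n_found}, and the
#'   per-gene scan list.
#' @export
planted_exon_recall <- function(corpus, model, report_threshold = 0, ...) {
  scans <- lapply(names(corpus$genes), function(g) {
    scan_sequence(corpus$genes[[g]], model,
                  report_threshold = report_threshold,
                  sequence_id = g, ...)
  })
  names(scans) <- names(corpus$genes)
  found <- vapply(seq_len(nrow(corpus$truth)), function(i) {
    tr <- corpus$truth[i, ]
    ex <- scans[[tr$gene]]$exons
    ex <- ex[ex$reported, , drop = FALSE]
    any(ex$acceptor_pos == tr$acceptor_pos & ex$donor_pos == tr$donor_pos)
  }, logical(1))
  list(recall = mean(found), n_true = length(found), n_found = sum(found),
       scans = scans)
}
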