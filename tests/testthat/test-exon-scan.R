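# Candidate enumeration, the scanning pipeline, pseudoexon extraction.

test_that("candidate enumeration applies the 6..399 nt distance rule", {
  sites <- rbind(make_call(100, kind = "acceptor"),
                 make_call(150, kind = "donor_GT"),
                 make_call(600, kind = "donor_GT"))
  pairs <- enumerate_candidate_exons(sites)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$length, 50L)

  # a donor only 3 nt downstream is excluded ("longer than 5 nt")
  sites2 <- rbind(make_call(100, kind = "acceptor"),
                  make_call(103, kind = "donor_GT"))
  expect_equal(nrow(enumerate_candidate_exons(sites2)), 0L)
  # boundary lengths 6 and 399 are admissible
  sites3 <- rbind(make_call(100, kind = "acceptor"),
                  make_call(106, kind = "donor_GT"),
                  make_call(499, kind = "donor_GT"))
  expect_equal(enumerate_candidate_exons(sites3)$length, c(6L, 399L))
})

test_that("candidate enumeration equals the brute-force double loop", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    sites <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_call(sample(0:700, 1),
                kind = sample(c("acceptor", "donor_GT", "donor_GC"), 1))
    }))
    sites <- sites[order(sites$position), ]
    pairs <- enumerate_candidate_exons(sites)
    brute <- 0L
    for (i in seq_len(nrow(sites))) {
      for (j in seq_len(nrow(sites))) {
        if (sites$kind[i] == "acceptor" && sites$kind[j] != "acceptor") {
          len <- sites$position[j] - sites$position[i]
          if (len >= 6L && len <= 399L) brute <- brute + 1L
        }
      }
    }
    expect_equal(nrow(pairs), brute)
  }
  # a acceptors and d donors mutually in range give a*d pairs
  sites <- rbind(make_call(10, kind = "acceptor"),
                 make_call(20, kind = "acceptor"),
                 make_call(120, kind = "donor_GT"),
                 make_call(150, kind = "donor_GC"),
                 make_call(180, kind = "donor_GT"))
  expect_equal(nrow(enumerate_candidate_exons(sites)), 6L)
})

test_that("scan pipeline finds planted exons and is deterministic", {
  corpus <- small_corpus()
  model <- small_model()
  g <- corpus$genes[[1]]
  res <- scan_sequence(g, model, report_threshold = 0,
                       sequence_id = "g1")
  truth <- corpus$truth[corpus$truth$gene == "gene001", ]
  for (i in seq_len(nrow(truth))) {
    expect_true(any(res$exons$acceptor_pos == truth$acceptor_pos[i] &
                      res$exons$donor_pos == truth$donor_pos[i]))
  }
  res2 <- scan_sequence(g, model, report_threshold = 0,
                        sequence_id = "g1")
  expect_identical(res, res2)

  # negative control: a pure random sequence still scans cleanly
  set.seed(1)
  rnd <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
               collapse = "")
  expect_s3_class(scan_sequence(rnd, model), "scan_result")
})

test_that("exons below the report threshold stay available programmatically", {
  model <- small_model()
  corpus <- small_corpus()
  res <- scan_sequence(corpus$genes[[2]], model, report_threshold = 1)
  expect_true(all(!res$exons$reported) || nrow(res$exons) == 0L)
  res0 <- scan_sequence(corpus$genes[[2]], model, report_threshold = 0)
  expect_equal(nrow(res0$exons), nrow(res$exons))
  expect_true(all(res0$exons$reported) || nrow(res0$exons) == 0L)
})

test_that("pseudoexon extraction honours interior, score and length rules", {
  model <- small_model()
  expect_equal(nrow(extract_pseudoexons(strrep("ACGT", 62), model$sensors)),
               0L)

  # planted decoy pair with posterior sum 0.04 is excluded; 0.5+0.5 passes
  acc_w <- train_oligo_model(rep("TTTTTTTTTTTTTTTTAGGGG", 1),
                             rep("TTTTTTTTTTTTTTTTAGGGG", 49),
                             "acceptor")       # posterior 0.02
  don_w <- train_oligo_model(rep("AAAGTATTT", 1), rep("AAAGTATTT", 49),
                             "donor_GT")        # posterior 0.02
  acc_s <- train_oligo_model("CCCCCCCCCCCCCCCCAGCCC",
                             "CCCCCCCCCCCCCCCCAGCCC", "acceptor")  # 0.5
  don_s <- train_oligo_model("GGGGTGGGG", "GGGGTGGGG", "donor_GT") # 0.5
  intron <- strrep("A", 1200)
  plant <- function(s, at0, oligo) {  # at0 = 0-based oligo start
    substr(s, at0 + 1L, at0 + nchar(oligo)) <- oligo
    s
  }
  intron <- plant(intron, 382, "TTTTTTTTTTTTTTTTAGGGG")  # weak acc at 400
  intron <- plant(intron, 447, "AAAGTATTT")              # weak don at 450
  intron <- plant(intron, 582, "CCCCCCCCCCCCCCCCAGCCC")  # strong acc at 600
  intron <- plant(intron, 637, "GGGGTGGGG")              # strong don at 640
  px <- extract_pseudoexons(intron, list(acc_w, don_w, acc_s, don_s))
  expect_false(any(px$acceptor_pos == 400 & px$donor_pos == 450))
  expect_true(any(px$acceptor_pos == 600 & px$donor_pos == 640))
  expect_true(all(px$score_sum > 0.05))
  expect_true(all(px$length > 5 & px$length < 400))
  expect_true(all(px$acceptor_pos - 205 >= 150))
})

test_that("duplicate pseudoexon contexts are discarded", {
  acc_s <- train_oligo_model("CCCCCCCCCCCCCCCCAGCCC",
                             "CCCCCCCCCCCCCCCCAGCCC", "acceptor")
  don_s <- train_oligo_model("GGGGTGGGG", "GGGGTGGGG", "donor_GT")
  cassette <- paste0("CCCCCCCCCCCCCCCCAGCCC", strrep("A", 10), "GGGGTGGGG")
  intron <- strrep("T", 1500)
  substr(intron, 401, 400 + nchar(cassette)) <- cassette
  substr(intron, 801, 800 + nchar(cassette)) <- cassette
  px <- extract_pseudoexons(intron, list(acc_s, don_s))
  # the two planted cassettes give identical 16-nt bodies; one survives
  expect_equal(sum(px$length == 16), 1L)
})

test_that("decoy pseudoexons far outnumber the planted exons", {
  corpus <- small_corpus()
  sensors <- list(
    train_oligo_model(corpus$true_acceptor_oligos,
                      harvest_decoy_oligos(corpus, "acceptor"),
                      "acceptor", pseudocount = 0.5),
    train_oligo_model(corpus$true_donor_oligos[
      corpus$true_donor_kinds == "donor_GT"],
      harvest_decoy_oligos(corpus, "donor_GT"),
      "donor_GT", pseudocount = 0.5))
  n_pseudo <- sum(vapply(corpus$introns, function(i) {
    nrow(extract_pseudoexons(i, sensors))
  }, numeric(1)))
  expect_gte(n_pseudo, 10 * nrow(corpus$truth))
})

test_that("scan results export as parseable GFF3", {
  model <- small_model()
  corpus <- small_corpus()
  res <- scan_sequence(corpus$genes[[1]], model, report_threshold = 0,
                       sequence_id = "gene001")
  path <- withr::local_tempfile(fileext = ".gff3")
  export_scan_gff3(res, path)
  gr <- rtracklayer::import(path)
  expect_setequal(unique(as.character(gr$type)),
                  c("splice_acceptor", "splice_donor", "predicted_exon"))
  ex <- gr[gr$type == "predicted_exon"]
  expect_equal(length(ex), sum(res$exons$reported))
  expect_true(all(!is.na(ex$total_lod)))
})
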