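# Variant application, coordinate maps, the seven-class event taxonomy,
# factor reports and enrichment tables.

test_that("SNVs edit one base under an identity coordinate map", {
  seq <- "ACGTACGTAC"
  v <- variant_spec(4, "T", "G")
  app <- apply_variant(seq, v)
  expect_equal(app$alt_seq, "ACGGACGTAC")
  expect_equal(app$ref_to_alt, 1:10)
  expect_equal(app$alt_to_ref, 1:10)
})

test_that("deletions shift downstream coordinates by the deleted width", {
  seq <- "ACGTACGTAC"
  app <- apply_variant(seq, variant_spec(5, "A", ""))
  expect_equal(nchar(app$alt_seq), 9L)
  expect_equal(app$ref_to_alt[4], 4L)
  expect_true(is.na(app$ref_to_alt[5]))
  expect_equal(app$ref_to_alt[6:10], 5:9)
})

test_that("ref-allele mismatches are reported with both alleles", {
  err <- tryCatch(apply_variant("ACGT", variant_spec(2, "G", "A")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "expected G")
  expect_match(err, "has C")
})

test_that("coordinate maps are monotone partial bijections that round-trip", {
  set.seed(19)
  for (rep in 1:50) {
    n <- sample(30:60, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    kind <- sample(c("SNV", "deletion", "insertion", "duplication"), 1)
    p <- sample(5:(n - 6), 1)
    w <- sample(1:4, 1)
    v <- switch(kind,
      SNV = {
        ref <- substr(seq, p, p)
        variant_spec(p, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1))
      },
      deletion = variant_spec(p, substr(seq, p, p + w - 1), ""),
      insertion = variant_spec(p, "", paste(
        sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")),
      duplication = {
        span <- substr(seq, p, p + w - 1)
        variant_spec(p, span, paste0(span, span), kind = "duplication")
      })
    app <- apply_variant(seq, v)
    fwd <- app$ref_to_alt; bwd <- app$alt_to_ref
    expect_equal(length(fwd), nchar(seq))
    expect_equal(length(bwd), nchar(app$alt_seq))
    def <- which(!is.na(fwd))
    expect_true(all(diff(fwd[def]) > 0))          # monotone
    expect_equal(bwd[fwd[def]], def)              # round trip
    def2 <- which(!is.na(bwd))
    expect_equal(fwd[bwd[def2]], def2)
    # mapped positions outside the edited span carry the same base
    untouched <- setdiff(def, seq(p, length.out = nchar(v$ref) + 1L))
    expect_equal(substring(app$alt_seq, fwd[untouched], fwd[untouched]),
                 substring(seq, untouched, untouched))
  }
})

test_that("IVS notation resolves against the exon annotation", {
  # exon1 1..100, exon2 201..300, exon3 401..500 (1-based)
  ann <- data.frame(start = c(1L, 201L, 401L), end = c(100L, 300L, 500L))
  seq <- strrep("A", 600)
  substr(seq, 302, 302) <- "C"
  v <- parse_ivs_variant("IVS2+2delC", ann, seq = seq)
  expect_equal(v$pos, 302L)
  expect_equal(v$kind, "deletion")
  expect_equal(v$ref, "C")

  v2 <- parse_ivs_variant("IVS1+1G>A", ann)
  expect_equal(v2$pos, 101L)
  expect_equal(v2$kind, "SNV")

  v3 <- parse_ivs_variant("IVS1-1G>T", ann)
  expect_equal(v3$pos, 200L)

  seq4 <- strrep("A", 600)
  substr(seq4, 103, 106) <- "GGGT"
  v4 <- parse_ivs_variant("IVS1+3_6dup(GGGT)", ann, seq = seq4)
  expect_equal(v4$pos, 103L)
  expect_equal(v4$kind, "duplication")
  expect_equal(v4$ref, "GGGT")
  expect_equal(v4$alt, "GGGTGGGT")
  app <- apply_variant(seq4, v4)
  expect_equal(nchar(app$alt_seq), 604L)

  expect_error(parse_ivs_variant("IVS9+1G>A", ann), "intron")
  expect_error(parse_ivs_variant("garbage", ann), "parse")
})

test_that("identical scans yield no events", {
  sc <- fake_scan(rbind(fake_exon(100, 220), fake_exon(300, 380)))
  ev <- classify_events(sc, sc, identity_map(500),
                        data.frame(start = 101, end = 220))
  expect_equal(nrow(ev), 0L)
})

test_that("event classes follow the annotated > shared-SS > generic precedence", {
  ann <- data.frame(start = 101, end = 220)  # acceptor 100, donor 220
  map <- identity_map(600)

  # annotated exon present in ref, absent in alt
  ev <- classify_events(fake_scan(fake_exon(100, 220)),
                        fake_scan(fake_exon(100, 220)[0, ]), map, ann)
  expect_equal(ev$event_class, "annotated_exon_disappears")

  # exon sharing only its acceptor with the annotation, lost
  ev2 <- classify_events(fake_scan(fake_exon(100, 180)),
                         fake_scan(fake_exon(100, 180)[0, ]), map, ann)
  expect_equal(ev2$event_class, "shared_ss_exon_disappears")

  # unrelated exon lost
  ev3 <- classify_events(fake_scan(fake_exon(300, 380)),
                         fake_scan(fake_exon(300, 380)[0, ]), map, ann)
  expect_equal(ev3$event_class, "exon_disappears")

  # new exon sharing a boundary / unrelated new exon
  ev4 <- classify_events(fake_scan(fake_exon(100, 220)[0, ]),
                         fake_scan(fake_exon(100, 180)), map, ann)
  expect_equal(ev4$event_class, "cryptic_exon_created_shared_ss")
  ev5 <- classify_events(fake_scan(fake_exon(100, 220)[0, ]),
                         fake_scan(fake_exon(300, 380)), map, ann)
  expect_equal(ev5$event_class, "cryptic_exon_created")

  # score changes above and below the 2% rule
  ev6 <- classify_events(fake_scan(fake_exon(100, 220, score = 0.50)),
                         fake_scan(fake_exon(100, 220, score = 0.56)),
                         map, ann)
  expect_equal(ev6$event_class, "annotated_exon_score_change")
  expect_equal(ev6$score_delta, 0.12)
  ev7 <- classify_events(fake_scan(fake_exon(100, 220, score = 0.50)),
                         fake_scan(fake_exon(100, 220, score = 0.505)),
                         map, ann)
  expect_equal(nrow(ev7), 0L)
  ev8 <- classify_events(fake_scan(fake_exon(100, 180, score = 0.50)),
                         fake_scan(fake_exon(100, 180, score = 0.40)),
                         map, ann)
  expect_equal(ev8$event_class, "shared_ss_exon_score_change")
  # score changes without any annotated anchor are not taxonomy events
  ev9 <- classify_events(fake_scan(fake_exon(300, 380, score = 0.50)),
                         fake_scan(fake_exon(300, 380, score = 0.80)),
                         map, ann)
  expect_equal(nrow(ev9), 0L)
})

test_that("every changed exon is assigned exactly one event class", {
  set.seed(29)
  ann <- data.frame(start = c(101, 301), end = c(180, 360))
  for (rep in 1:30) {
    mk <- function() {
      n <- sample(0:6, 1)
      if (n == 0) return(fake_exon(0, 10)[0, ])
      acc <- sample(c(100, 300, seq(0, 500, by = 20)), n)
      do.call(rbind, lapply(acc, function(a) {
        fake_exon(a, a + sample(c(60, 80, 120), 1),
                  score = runif(1, 0.1, 1))
      }))
    }
    ref <- mk(); alt <- mk()
    ev <- classify_events(fake_scan(ref), fake_scan(alt),
                          identity_map(700), ann)
    expect_true(all(ev$event_class %in%
                      c("annotated_exon_disappears",
                        "annotated_exon_score_change",
                        "shared_ss_exon_score_change",
                        "shared_ss_exon_disappears",
                        "cryptic_exon_created_shared_ss",
                        "exon_disappears", "cryptic_exon_created")))
    ref_keys <- paste(ev$ref_acceptor, ev$ref_donor)
    alt_keys <- paste(ev$alt_acceptor, ev$alt_donor)
    expect_false(any(duplicated(ref_keys[!grepl("NA", ref_keys)])))
    expect_false(any(duplicated(alt_keys[!grepl("NA", alt_keys)])))
  }
})

test_that("swapping ref and alt swaps loss and creation classes", {
  ann <- data.frame(start = 101, end = 220)
  map <- identity_map(600)
  a <- fake_scan(fake_exon(100, 180))
  b <- fake_scan(fake_exon(100, 180)[0, ])
  fwd <- classify_events(a, b, map, ann)
  rev <- classify_events(b, a, map, ann)
  expect_equal(fwd$event_class, "shared_ss_exon_disappears")
  expect_equal(rev$event_class, "cryptic_exon_created_shared_ss")

  a2 <- fake_scan(fake_exon(300, 380))
  fwd2 <- classify_events(a2, b, map, ann)
  rev2 <- classify_events(b, a2, map, ann)
  expect_equal(fwd2$event_class, "exon_disappears")
  expect_equal(rev2$event_class, "cryptic_exon_created")
})

test_that("a no-op variant produces no events end to end", {
  model <- variant_model()
  cases <- generate_variant_cases(1, seed = 5)
  cs <- cases[[1]]
  same <- apply_variant(cs$seq, variant_spec(1, substr(cs$seq, 1, 1),
                                             substr(cs$seq, 1, 1),
                                             kind = "deletion"))
  ref <- scan_sequence(cs$seq, model, report_threshold = 0)
  # identical sequence scanned twice through an identity map
  ev <- classify_events(ref, ref, identity_map(nchar(cs$seq)),
                        cs$annotation)
  expect_equal(nrow(ev), 0L)
})

test_that("factor reports list every component and add up to the total", {
  acc <- make_call(100, kind = "acceptor", posterior = 0.5)
  don <- make_call(180, kind = "donor_GT", posterior = 0.5)
  neutral <- score_exon(acc, don, length_model = uniform_length_model())
  rep_txt <- report_factors(neutral)
  expect_match(rep_txt, "total LOD \\+0\\.0000")
  expect_match(rep_txt, "elements \\(0 resolved")

  hits <- make_hit(150, 1.1, motif = "GGGGTGGG", class = "ISE")
  comp <- make_call(200, kind = "donor_GT", posterior = 0.9)
  ex <- score_exon(make_call(100, kind = "acceptor", posterior = 0.8),
                   make_call(180, kind = "donor_GT", posterior = 0.7),
                   element_hits = hits, competitor_hits = comp,
                   length_model = uniform_length_model())
  txt <- report_factors(ex)
  expect_equal(length(gregexpr("GGGGTGGG", txt)[[1]]), 1L)
  # parse the printed component sum and compare with the printed total
  sum_line <- grep("total LOD", strsplit(txt, "\n")[[1]], value = TRUE)
  nums <- as.numeric(regmatches(sum_line,
                                gregexpr("[+-]\\d+\\.\\d+", sum_line))[[1]])
  expect_equal(nums[1], sum(nums[-1]), tolerance = 1e-3)
})

test_that("enrichment tables reproduce counts and two-decimal ratios", {
  ev_from_counts <- function(counts) {
    rep(c("annotated_exon_disappears", "annotated_exon_score_change",
          "shared_ss_exon_score_change", "shared_ss_exon_disappears",
          "cryptic_exon_created_shared_ss", "exon_disappears",
          "cryptic_exon_created"), counts)
  }
  tab <- enrichment_table(list(
    disease = ev_from_counts(c(0, 43, 242, 23, 26, 50, 50)),
    control = ev_from_counts(c(2, 12, 78, 4, 9, 49, 46))))
  expect_equal(tab$disease, c(0, 43, 242, 23, 26, 50, 50))
  expect_equal(tab$control, c(2, 12, 78, 4, 9, 49, 46))
  r <- tab$ratio_disease_vs_control
  expect_equal(r[2], "3.58")
  expect_equal(r[4], "5.75")
  expect_equal(r[1], "0.00")

  tab2 <- enrichment_table(list(a = ev_from_counts(c(0, 5, 0, 0, 0, 0, 0)),
                                b = ev_from_counts(c(0, 5, 0, 0, 0, 0, 0))))
  expect_equal(tab2$ratio_a_vs_b[2], "1.00")
  expect_equal(tab2$ratio_a_vs_b[1], "-")
})
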