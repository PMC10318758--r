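# toy_model(): G1 (+) exons 100-200, 500-1000, 5000-5200
#               G2 (-) exons 40000-40200, 50000-50300, 57800-58000

test_that("a deletion linking two flanking introns is matched at intron_exact", {
  model <- toy_model()
  # 5' break after G1 exon 2 (intron 1001..4999); 3' break before G2
  # transcript exon 2 (genomic intron 50301..57799, expected ori left)
  pred <- make_prediction("G1", "G2", 1000L, 50300L, "+", "-")
  sv <- make_sv("tg1", 2500, "left", "tg1", 55000, "left", id = "sv1")
  sup <- match_fusion_to_svs(pred, model, sv)
  expect_equal(nrow(sup), 1)
  expect_equal(sup$level5, "intron_exact")
  expect_equal(sup$level3, "intron_exact")
  expect_equal(sup$dist5, 1500)
  expect_equal(sup$dist3, 4700)
  expect_true(sup$orientation_ok)
})

test_that("SVs confined to one partner gene never support a fusion", {
  model <- toy_model()
  pred <- make_prediction("G1", "G2", 1000L, 50300L, "+", "-")
  sv <- make_sv("tg1", 300, "left", "tg1", 4000, "right", id = "svA")
  expect_equal(nrow(match_fusion_to_svs(pred, model, sv)), 0)
})

test_that("wrong breakend orientations are rejected", {
  model <- toy_model()
  pred <- make_prediction("G1", "G2", 1000L, 50300L, "+", "-")
  # correct positions, inverted orientations: inconsistent with the
  # observed chimeric transcript
  sv <- make_sv("tg1", 2500, "right", "tg1", 55000, "right", id = "svB")
  expect_equal(nrow(match_fusion_to_svs(pred, model, sv)), 0)
})

test_that("a missing partner gene yields a reason code", {
  model <- toy_model()
  pred <- make_prediction("G1", "GHOST", 1000L, 50300L)
  sup <- match_fusion_to_svs(pred, model, make_sv("tg1", 1, "left", "tg1", 2, "right"))
  expect_equal(nrow(sup), 0)
  expect_equal(attr(sup, "reason"), "no_transcript")
})

test_that("indexed matching equals the brute-force all-pairs scan", {
  sc <- shared_cohort()
  model <- sc$res$model
  # one busy patient: every merged prediction against all of its SVs
  pdir <- file.path(sc$dir, "patients", "P01")
  a <- read_star_fusion(file.path(pdir, "star_fusion.tsv"), "P01")
  b <- read_fusioncatcher(file.path(pdir, "fusioncatcher.tsv"), "P01", 1e8)
  merged <- merge_predictions(a, b)
  svs <- do.call(rbind, lapply(c("manta", "delly", "gridss"), function(cl) {
    read_sv_vcf(file.path(pdir, paste0(cl, ".vcf")), cl)
  }))
  expect_lte(nrow(svs), 50)
  expect_lte(nrow(merged), 20)
  for (i in seq_len(nrow(merged))) {
    pred <- merged[i, , drop = FALSE]
    got <- match_fusion_to_svs(pred, model, svs)
    want <- brute_force_supports(pred, model, svs)
    expect_same_ids(got$sv_id, names(want))
    for (j in seq_len(nrow(got))) {
      w <- want[[got$sv_id[j]]]
      expect_equal(got$level5[j], w$level5)
      expect_equal(got$level3[j], w$level3)
      expect_equal(got$dist5[j] + got$dist3[j], w$dist5 + w$dist3)
    }
  }
})

test_that("reciprocal overlap matches direct arithmetic", {
  expect_equal(reciprocal_overlap(100, 199, 100, 199), 1.0)
  expect_equal(reciprocal_overlap(100, 199, 300, 400), 0.0)
  expect_equal(reciprocal_overlap(100, 199, 150, 249), 0.5)
  set.seed(7)
  for (i in 1:1000) {
    a <- sort(sample.int(500, 2)); b <- sort(sample.int(500, 2))
    # enumeration oracle: count shared integer positions
    shared <- length(intersect(a[1]:a[2], b[1]:b[2]))
    want <- min(shared / (a[2] - a[1] + 1), shared / (b[2] - b[1] + 1))
    expect_equal(reciprocal_overlap(a[1], a[2], b[1], b[2]), want)
  }
})

test_that("breakpoint distance is chromosome-guarded", {
  expect_equal(breakpoint_distance("tg1", 1000, "tg1", 1000), 0)
  expect_equal(breakpoint_distance("tg1", 1000, "tg1", 1500), 500)
  expect_error(breakpoint_distance("tg1", 1, "tg2", 1), "chromosome")
})

test_that("consensus requires two callers for high confidence", {
  model <- toy_model()
  pred <- make_prediction("G1", "G2", 1000L, 50300L, "+", "-")
  sv3 <- rbind(
    make_sv("tg1", 2500, "left", "tg1", 55000, "left", "manta", "m1"),
    make_sv("tg1", 2500, "left", "tg1", 55000, "left", "delly", "d1"),
    make_sv("tg1", 2500, "left", "tg1", 55000, "left", "gridss", "g1")
  )
  sup <- match_fusion_to_svs(pred, model, sv3)
  rf <- build_consensus(pred, sup, sv3)
  expect_equal(rf$n_sv_callers, 3)
  expect_true(rf$high_confidence)
  expect_false(rf$composite)
  expect_equal(rf$pos1, 2500)

  rf1 <- build_consensus(pred, sup[sup$caller == "manta", ], sv3)
  expect_equal(rf1$n_sv_callers, 1)
  expect_false(rf1$high_confidence)

  # single RNA caller: never high confidence regardless of SV support
  pred1 <- make_prediction("G1", "G2", 1000L, 50300L, "+", "-", both = FALSE)
  sup1 <- match_fusion_to_svs(pred1, model, sv3)
  rf_rna <- build_consensus(pred1, sup1, sv3)
  expect_false(rf_rna$high_confidence)

  expect_null(build_consensus(pred, sup[0, ], sv3))
})

test_that("translocation calls cluster by breakend proximity", {
  model <- toy_model()
  # place the 3' gene on tg1 but pretend caller positions differ by <=10bp
  pred <- make_prediction("G1", "G2", 1000L, 50300L, "+", "-")
  svs <- rbind(
    make_sv("tg1", 2500, "left", "tg1", 55000, "left", "manta", "m1"),
    make_sv("tg1", 2504, "left", "tg1", 55006, "left", "delly", "d1"),
    make_sv("tg1", 2498, "left", "tg1", 54995, "left", "gridss", "g1")
  )
  svs$sv_type <- "CTX"  # force breakend-proximity clustering
  svs$length <- NA_integer_
  sup <- match_fusion_to_svs(pred, model, svs)
  rf <- build_consensus(pred, sup, svs, fusion_config(ctx_max_dist = 10L))
  expect_equal(rf$n_sv_callers, 3)
  # consensus breakends are medians of the callers' positions
  expect_equal(rf$pos1, 2500)
  expect_equal(rf$pos2, 55000)
})

test_that("disagreeing clustered calls are flagged composite", {
  model <- toy_model()
  pred <- make_prediction("G1", "G2", 1000L, 50300L, "+", "-")
  svs <- rbind(
    make_sv("tg1", 2500, "left", "tg1", 55000, "left", "manta", "m1"),
    make_sv("tg1", 2500, "left", "tg1", 55000, "left", "manta", "m2"),
    make_sv("tg1", 2500, "left", "tg1", 55000, "left", "delly", "d1")
  )
  sup <- match_fusion_to_svs(pred, model, svs)
  rf <- build_consensus(pred, sup, svs)
  expect_true(rf$composite)  # one caller contributes a multi-call chain
  expect_equal(rf$n_sv_callers, 2)
})

test_that("somatic classification partitions tumor/normal AF space", {
  cfg <- fusion_config()
  expect_equal(classify_somatic(0.40, 0.00, cfg), "tumor_specific")
  expect_equal(classify_somatic(0.50, 0.48, cfg), "germline")
  expect_equal(classify_somatic(0.04, 0.00, cfg), "low_af")
  expect_equal(classify_somatic(NA, NA, cfg), "unclassified")
  expect_equal(classify_somatic(0.04, NA, cfg), "low_af")

  # every AF pair gets exactly one class
  grid <- expand.grid(t = seq(0, 1, by = 0.05), n = seq(0, 1, by = 0.05))
  cls <- classify_somatic(grid$t, grid$n, cfg)
  expect_true(all(cls %in% c("tumor_specific", "germline", "low_af")))

  # sweeping thresholds moves only boundary cases
  cfg2 <- fusion_config(tumor_af_min = 0.2)
  cls2 <- classify_somatic(grid$t, grid$n, cfg2)
  moved <- which(cls != cls2)
  expect_true(all(grid$t[moved] >= 0.1 & grid$t[moved] < 0.2))
})
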