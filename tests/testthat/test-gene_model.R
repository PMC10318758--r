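test_that("parse_gtf echoes a toy annotation faithfully", {
  model <- toy_model()
  expect_s3_class(model, "GeneModel")
  expect_equal(nrow(model$genes), 2)
  expect_equal(nrow(model$transcripts), 2)
  expect_equal(length(model$exons[["T1"]]), 3)
  expect_equal(BiocGenerics::start(model$exons[["T1"]]), c(100, 500, 5000))
  expect_setequal(model$transcripts$tags[[1]], c("basic", "CCDS", "MANE_Select"))
  expect_equal(model$transcripts$tsl, c(1L, 1L))
})

test_that("parse_gtf rejects malformed records naming the line", {
  lines <- toy_gtf_lines()
  bad <- sub("\t5200\t", "\t90\t", lines[1])  # end < start
  path <- tempfile(fileext = ".gtf")
  writeLines(c(bad, lines[-1]), path)
  expect_error(parse_gtf(path), "line 1")

  writeLines(c(lines[1], "tg1\ttoy\tgene\t1\t10"), path)
  expect_error(parse_gtf(path), "line 2")
})

test_that("records with unknown strand are flagged", {
  lines <- c(toy_gtf_lines(),
             "tg1\ttoy\tgene\t90000\t90100\t.\t.\t.\tgene_id \"G9\";")
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  w <- capture_warnings(parse_gtf(path))
  expect_true(any(grepl("unknown strand", w)))
})

test_that("canonical selection follows the stepwise filters", {
  # MANE Select is decisive regardless of everything else
  tx <- rbind(make_tx("T1", c("MANE_Select"), tsl = 5L, cds = 100L),
              make_tx("T2", c("basic", "CCDS"), tsl = 1L, cds = 5000L))
  expect_equal(select_canonical(tx)$transcript_id, "T1")

  # singleton comes back untouched
  single <- make_tx("Tonly", character(0), biotype = "lncRNA", cds = 0L)
  expect_equal(select_canonical(single)$transcript_id, "Tonly")

  # equal tags and TSL: longest coding sequence wins
  tx <- rbind(make_tx("T1", c("basic", "CCDS"), cds = 900L),
              make_tx("T2", c("basic", "CCDS"), cds = 1200L))
  expect_equal(select_canonical(tx)$transcript_id, "T2")

  # full tie: lexicographically smallest id
  tx <- rbind(make_tx("TB", c("basic")), make_tx("TA", c("basic")))
  expect_equal(select_canonical(tx)$transcript_id, "TA")

  # missing TSL ranks worst
  tx <- rbind(make_tx("T1", c("basic"), tsl = NA), make_tx("T2", c("basic"), tsl = 2L))
  expect_equal(select_canonical(tx)$transcript_id, "T2")
})

test_that("canonical selection matches exhaustive filtering on all tag combinations", {
  # oracle: literal stepwise filtering, written independently
  oracle <- function(tx) {
    steps <- list(
      function(t) vapply(t$tags, function(x) "MANE_Select" %in% x, TRUE),
      function(t) vapply(t$tags, function(x) "basic" %in% x, TRUE),
      function(t) vapply(t$tags, function(x) "CCDS" %in% x, TRUE),
      function(t) vapply(t$tags, function(x) any(grepl("^appris_principal", x)), TRUE),
      function(t) !is.na(t$biotype) & t$biotype == "protein_coding",
      function(t) ifelse(is.na(t$tsl), Inf, t$tsl) ==
        min(ifelse(is.na(t$tsl), Inf, t$tsl)),
      function(t) t$cds_length == max(t$cds_length)
    )
    for (s in steps) {
      keep <- s(tx)
      if (any(keep)) tx <- tx[keep, , drop = FALSE]
    }
    sort(tx$transcript_id)[1]
  }
  tag_universe <- c("MANE_Select", "basic", "CCDS", "appris_principal_1")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  tag_sets <- apply(combos, 1, function(on) tag_universe[as.logical(on)])

  set.seed(42)
  for (rep_i in 1:25) {
    n <- sample(2:5, 1)
    tx <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_tx(sprintf("T%02d", i),
              tags = tag_sets[[sample.int(length(tag_sets), 1)]],
              biotype = sample(c("protein_coding", "lncRNA"), 1),
              tsl = sample(c(NA, 1:5), 1),
              cds = sample(c(0L, 300L, 900L, 1500L), 1))
    }))
    expect_equal(select_canonical(tx)$transcript_id, oracle(tx))
    # permutation invariance
    perm <- tx[sample(nrow(tx)), , drop = FALSE]
    expect_equal(select_canonical(perm)$transcript_id, oracle(tx))
  }
})

test_that("matching intervals follow intron-exon structure on the plus strand", {
  model <- toy_model()
  # G1 (+): exon2 ends at 1000, exon3 starts at 5000
  mis <- derive_matching_intervals(model, "G1", 1000L, "five_prime")
  expect_true(mis$canonical_boundary)
  lv <- as.data.frame(mis$levels)
  intron <- lv[lv$level == "intron_exact", ]
  expect_equal(c(intron$start, intron$end), c(1001, 4999))
  expect_equal(lv[lv$level == "gene_body", c("start", "end")],
               data.frame(start = 100, end = 5200, row.names = 2L))
  expect_equal(mis$expected_orientation, "left")

  # 3' side of the same junction style: exon3 starts 5000, previous exon
  # ends 1000 -> same intron, opposite expected orientation
  mis3 <- derive_matching_intervals(model, "G1", 5000L, "three_prime")
  lv3 <- as.data.frame(mis3$levels)
  expect_equal(unlist(lv3[lv3$level == "intron_exact", c("start", "end")],
                      use.names = FALSE), c(1001, 4999))
  expect_equal(mis3$expected_orientation, "right")
})

test_that("matching intervals flip genomic direction on the minus strand", {
  model <- toy_model()
  # G2 (-): transcript-orientation exon 2 spans 50000-50300; its
  # transcript-orientation end is the genomic START (50000); the
  # following intron lies genomically upstream (40201..49999)
  mis <- derive_matching_intervals(model, "G2", 50000L, "five_prime")
  expect_true(mis$canonical_boundary)
  lv <- as.data.frame(mis$levels)
  intron <- lv[lv$level == "intron_exact", ]
  expect_equal(c(intron$start, intron$end), c(40201, 49999))
  expect_true(intron$end < 50000)  # genomically upstream of exon 2
  expect_equal(mis$expected_orientation, "right")
})

test_that("breakpoints off exon boundaries degrade to a flagged window", {
  model <- toy_model()
  mis <- derive_matching_intervals(model, "G1", 700L, "five_prime")
  expect_false(mis$canonical_boundary)
  lv <- as.data.frame(mis$levels)
  w <- lv[lv$level == "intron_exact", ]
  expect_true(w$start <= 700 && w$end >= 700)

  # boundary tolerance: 2 bp off still counts as the boundary
  mis_tol <- derive_matching_intervals(model, "G1", 1002L, "five_prime")
  expect_true(mis_tol$canonical_boundary)
})

test_that("breakpoints outside the flank yield an empty set with a reason", {
  model <- toy_model()
  mis <- derive_matching_intervals(model, "G1", 200000L, "five_prime")
  expect_equal(length(mis$levels), 0)
  expect_equal(mis$reason, "outside_gene_flank")
})

test_that("interval levels nest and exclude retained exonic bases", {
  sc <- shared_cohort()
  model <- sc$res$model
  truth <- sc$truth
  fus <- truth[truth$kind == "true_fusion", ]
  for (i in seq_len(nrow(fus))) {
    ev <- fus[i, ]
    for (side in c("five_prime", "three_prime")) {
      gid <- if (side == "five_prime") ev$gene5_id else ev$gene3_id
      pos <- if (side == "five_prime") ev$rna_bp5 else ev$rna_bp3
      mis <- derive_matching_intervals(model, gid, pos, side)
      lv <- as.data.frame(mis$levels)
      stopifnot(nrow(lv) == 3)
      ie <- lv[lv$level == "intron_exact", ]
      gb <- lv[lv$level == "gene_body", ]
      gf <- lv[lv$level == "gene_flank", ]
      expect_true(ie$start >= gb$start && ie$end <= gb$end)
      expect_true(gb$start >= gf$start && gb$end <= gf$end)
      # no exonic base of the canonical transcript inside intron_exact
      ex <- model$exons[[mis$transcript_id]]
      ov <- IRanges::overlapsAny(
        IRanges::IRanges(ie$start, ie$end),
        IRanges::ranges(ex))
      expect_false(any(ov))
    }
  }
})

test_that("interval membership equals a position-by-position enumeration", {
  model <- toy_model()
  cfg <- fusion_config(flank_bp = 500L)
  mis <- derive_matching_intervals(model, "G1", 1000L, "five_prime", cfg)
  lv <- as.data.frame(mis$levels)
  for (pos in seq(1, 6200, by = 7)) {
    for (r in seq_len(nrow(lv))) {
      inside <- pos >= lv$start[r] & pos <= lv$end[r]
      gr <- GenomicRanges::GRanges("tg1", IRanges::IRanges(pos, pos))
      expect_equal(
        length(GenomicRanges::findOverlaps(gr, mis$levels[r])) > 0,
        inside
      )
    }
  }
})
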