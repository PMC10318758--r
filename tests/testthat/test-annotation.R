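write_tsv <- function(df) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

toy_resources <- function(cfg = fusion_config()) {
  load_annotation_resources(
    healthy_chimera = write_tsv(data.frame(gene5 = "CCDC32", gene3 = "CBX3")),
    cancer_chimera = write_tsv(data.frame(gene5 = c("FRS2", "FRS2"),
                                          gene3 = c("PTPRR", "MDM1"))),
    population_svs = write_tsv(data.frame(
      chrom = "tg1", start = c(1000, 50000), end = c(2000, 60000),
      sv_type = c("DEL", "DUP"))),
    repeats = write_tsv(data.frame(
      chrom = "tg1",
      start = c(900, 5000, 7000, 9000),
      end = c(1200, 5400, 7400, 9400),
      repeat_class = c("SINE", "LINE", "Simple_repeat", "SINE"),
      repeat_family = c("AluY", "L1", "(AT)n", "AluSx"),
      bp_missing = c(4, 10, 0, 900))),
    segdups = write_tsv(data.frame(chrom = "tg1", start = 30000, end = 40000)),
    gene_lists = write_tsv(data.frame(
      gene = c("TP53", "BRAF", "BRAF", "EWSR1"),
      category = c("tsg", "oncogene", "kinase", "clinically_relevant"))),
    cfg = cfg
  )
}

test_that("chimera lists match exact oriented gene pairs", {
  res <- toy_resources()
  fl <- annotate_chimera("CCDC32", "CBX3", res)
  expect_true(fl[["healthy_chimera"]])
  expect_false(fl[["cancer_chimera"]])
  expect_true(annotate_chimera("FRS2", "PTPRR", res)[["cancer_chimera"]])
  # orientation-sensitive by default; symmetric only on request
  expect_false(annotate_chimera("CBX3", "CCDC32", res)[["healthy_chimera"]])
  expect_true(annotate_chimera("CBX3", "CCDC32", res,
                               symmetric = TRUE)[["healthy_chimera"]])
  none <- annotate_chimera("AAA", "BBB", res)
  expect_false(any(none))
  # caller-provided healthy flag propagates
  expect_true(annotate_chimera("AAA", "BBB", res,
                               caller_healthy_flag = TRUE)[["healthy_chimera"]])
})

test_that("population SV matching needs >50% reciprocal overlap and a span", {
  res <- toy_resources()
  hit <- make_sv("tg1", 1000, "left", "tg1", 2000, "right")
  expect_true(annotate_population_sv(hit, res))
  # 49% reciprocal overlap stays below the criterion
  L <- 1001
  shift <- ceiling(0.51 * L)
  near <- make_sv("tg1", 1000 + shift, "left", "tg1", 2000 + shift, "right")
  expect_equal(reciprocal_overlap(1000, 2000, near$pos1, near$pos2), 0.49,
               tolerance = 0.005)
  expect_false(annotate_population_sv(near, res))
  # translocations have no span
  ctx <- make_sv("tg1", 1000, "left", "tg2", 2000, "right")
  expect_false(annotate_population_sv(ctx, res))
  # type-aware: a DUP over the DEL interval is not the same variant
  dup <- make_sv("tg1", 1000, "right", "tg1", 2000, "left")
  expect_equal(dup$sv_type, "DUP")
  expect_false(annotate_population_sv(dup, res))
  expect_true(annotate_population_sv(
    dup, res, fusion_config(popsv_type_aware = FALSE)))
})

test_that("repeat annotation uses the pre-filtered track", {
  res <- toy_resources()
  # class filter: Simple_repeat removed; completeness: AluSx (900 bp
  # missing) removed under the default max_remaining rule
  expect_equal(length(res$repeats), 2)
  f <- make_sv("tg1", 1000, "left", "tg1", 5100, "right")
  hits <- annotate_repeats(f, res)
  expect_equal(hits$repeat5, "SINE")
  expect_equal(hits$repeat3, "LINE")
  f2 <- make_sv("tg1", 20000, "left", "tg1", 35000, "right")
  hits2 <- annotate_repeats(f2, res)
  expect_equal(hits2$repeat5, "")
  expect_true(hits2$segdup3)
  expect_false(hits2$segdup5)
  # the alternate completeness reading keeps the truncated element instead
  res_min <- toy_resources(fusion_config(repeat_completeness_mode = "min_remaining"))
  expect_true("AluSx" %in% S4Vectors::mcols(res_min$repeats)$repeat_family)
})

test_that("cancer-gene lists flag partners and the fusion", {
  res <- toy_resources()
  fl <- annotate_cancer_genes("TP53", "BRAF", res)
  expect_true(fl[["tsg5"]])
  expect_true(fl[["onco3"]])
  expect_true(fl[["kinase3"]])
  expect_true(fl[["onco_or_tsg"]])
  expect_false(any(annotate_cancer_genes("AAA", "BBB", res)))
})

test_that("annotation decorates without changing calls", {
  sc <- shared_cohort()
  plain <- suppressWarnings(resolve_cohort_dir(sc$dir, annotate = FALSE))
  annotated <- sc$res
  for (p in names(annotated$runs)) {
    a <- annotated$runs[[p]]$report
    b <- plain$runs[[p]]$report
    expect_equal(a$somatic_class, b$somatic_class)
    expect_equal(a$high_confidence, b$high_confidence)
  }
})

test_that("distinct mapping conserves totals and counts recurrence", {
  fus <- data.frame(
    patient_id = c("p1", "p2", "p3", "p1", "p1"),
    gene5_name = c("A", "A", "A", "B", "C"),
    gene3_name = c("X", "X", "X", "Y", "Z"),
    somatic_class = c("tumor_specific", "tumor_specific", "germline",
                      "tumor_specific", "low_af"),
    high_confidence = TRUE,
    stringsAsFactors = FALSE
  )
  d <- map_to_distinct(fus)
  expect_equal(nrow(d), 3)
  expect_equal(sum(d$recurrence), nrow(fus))
  ax <- d[d$gene5_name == "A", ]
  expect_equal(ax$n_patients, 3)
  expect_equal(ax$somatic_class, "tumor_specific")
  expect_true(ax$class_conflict)
  expect_false(d$class_conflict[d$gene5_name == "B"])
  # single patient: distinct equals per-patient
  d1 <- map_to_distinct(fus[fus$patient_id == "p1", ])
  expect_equal(nrow(d1), 3)
  expect_true(all(d1$recurrence == 1))
})
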