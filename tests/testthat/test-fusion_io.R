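sf_header <- paste("#FusionName", "JunctionReadCount", "SpanningFragCount",
                   "LeftGene", "LeftBreakpoint", "RightGene",
                   "RightBreakpoint", "FFPM", "annots", sep = "\t")

empty_predictions_for_test <- function() {
  p <- tempfile()
  writeLines(sf_header, p)
  read_star_fusion(p)
}

test_that("STAR-Fusion-style tables are normalized", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    sf_header,
    paste("AA--BB", 3, 5, "AA^G001", "tg1:1000:+", "BB^G002", "tg2:900:-",
          "0.08", "GTEx_recurrent", sep = "\t"),
    paste("CC--DD", 2, 0, "CC^G003", "tg1:500:+", "DD^G004", "tg1:9000:+",
          "1.25", ".", sep = "\t")
  ), path)
  preds <- read_star_fusion(path, "pt1")
  expect_equal(nrow(preds), 2)
  expect_equal(preds$ffpm[1], 0.08)
  expect_equal(preds$gene5_id[1], "G001")
  expect_equal(preds$gene5_name[1], "AA")
  expect_equal(preds$pos3[1], 900L)
  expect_equal(preds$strand3[1], "-")
  expect_true(preds$healthy_flag[1])
  expect_false(preds$healthy_flag[2])
})

test_that("empty and malformed RNA inputs are handled", {
  path <- tempfile(fileext = ".tsv")
  writeLines(sf_header, path)
  expect_equal(nrow(read_star_fusion(path)), 0)

  writeLines("#FusionName\tLeftGene", path)
  expect_error(read_star_fusion(path), "JunctionReadCount")
})

test_that("FusionCatcher-style tables are normalized and FFPM derived", {
  path <- tempfile(fileext = ".tsv")
  header <- paste("Gene_1_symbol(5end_fusion_partner)",
                  "Gene_2_symbol(3end_fusion_partner)", "Fusion_description",
                  "Spanning_pairs", "Spanning_unique_reads",
                  "Fusion_point_for_gene_1(5end_fusion_partner)",
                  "Fusion_point_for_gene_2(3end_fusion_partner)",
                  "Gene_1_id(5end_fusion_partner)",
                  "Gene_2_id(3end_fusion_partner)", sep = "\t")
  writeLines(c(
    header,
    paste("AA", "BB", "healthy", 4, 4, "tg1:1000:+", "tg2:900:-",
          "G001", "G002", sep = "\t"),
    paste("CC", "DD", ".", 1, 2, "tg1:500", "tg1:9000", "G003", "G004",
          sep = "\t")
  ), path)
  preds <- read_fusioncatcher(path, "pt1", total_fragments = 1e8)
  expect_equal(nrow(preds), 2)
  expect_equal(preds$ffpm[1], (4 + 4) / 1e8 * 1e6)
  expect_true(preds$healthy_flag[1])
  # strand-less fusion point accepted with missing strand
  expect_true(is.na(preds$strand5[2]))
  # without a library size FFPM stays missing
  preds2 <- read_fusioncatcher(path, "pt1")
  expect_true(all(is.na(preds2$ffpm)))

  writeLines(paste("Gene_1_symbol(5end_fusion_partner)", "x", sep = "\t"), path)
  expect_error(read_fusioncatcher(path), "mandatory column")
})

test_that("FFPM arithmetic and its guard rails", {
  expect_equal(compute_ffpm(3, 30e6), 0.1)
  expect_equal(compute_ffpm(0, 30e6), 0)
  expect_equal(compute_ffpm(24, 300e6), 0.08)
  expect_error(compute_ffpm(3, 0), "total_fragments")
  # linear in supporting fragments
  expect_equal(compute_ffpm(1:10, 1e8), (1:10) / 1e8 * 1e6)
})

test_that("predictions merge on oriented gene pairs", {
  a <- read_star_fusion({
    p <- tempfile(); writeLines(c(
      sf_header,
      paste("X--Y", 3, 5, "X^GX", "tg1:1000:+", "Y^GY", "tg1:9002:+",
            "0.50", ".", sep = "\t")), p); p
  }, "pt")
  b_path <- tempfile()
  header <- paste("Gene_1_symbol(5end_fusion_partner)",
                  "Gene_2_symbol(3end_fusion_partner)", "Fusion_description",
                  "Spanning_pairs", "Spanning_unique_reads",
                  "Fusion_point_for_gene_1(5end_fusion_partner)",
                  "Fusion_point_for_gene_2(3end_fusion_partner)",
                  "Gene_1_id(5end_fusion_partner)",
                  "Gene_2_id(3end_fusion_partner)", sep = "\t")
  writeLines(c(header,
    paste("X", "Y", ".", 10, 10, "tg1:1002:+", "tg1:9000:+", "GX", "GY",
          sep = "\t"),
    paste("Y", "X", ".", 2, 2, "tg1:9000:-", "tg1:1002:-", "GY", "GX",
          sep = "\t")), b_path)
  b <- read_fusioncatcher(b_path, "pt", total_fragments = 1e8)

  merged <- merge_predictions(a, b)
  # (X,Y) collapses across callers; (Y,X) is a distinct reciprocal fusion
  expect_equal(nrow(merged), 2)
  xy <- merged[merged$gene5_id == "GX", ]
  expect_true(xy$predicted_by_both)
  expect_equal(nrow(xy$breakpoints[[1]]), 2)  # both breakpoint sets kept
  expect_equal(xy$max_ffpm, 0.5)
  yx <- merged[merged$gene5_id == "GY", ]
  expect_false(yx$predicted_by_both)

  # one caller only
  merged_a <- merge_predictions(a, empty_predictions_for_test())
  expect_equal(nrow(merged_a), 1)
  expect_false(merged_a$predicted_by_both)
  # re-merging with nothing is idempotent on the count
  expect_lte(nrow(merged), nrow(a) + nrow(b))
})

test_that("low expression is a flag, never a filter", {
  p <- tempfile()
  writeLines(c(
    sf_header,
    paste("L--M", 1, 2, "L^GL", "tg1:100:+", "M^GM", "tg1:900:+",
          "0.03", ".", sep = "\t")), p)
  a <- read_star_fusion(p, "pt")
  merged <- merge_predictions(a, empty_predictions_for_test())
  expect_equal(nrow(merged), 1)       # survives merging
  expect_true(merged$low_expression)  # but is flagged
})
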