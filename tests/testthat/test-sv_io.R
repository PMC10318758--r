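vcf_header <- function(extra_formats) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=CT,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"t\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"t\">",
    extra_formats,
    "##contig=<ID=tg1>", "##contig=<ID=tg2>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR")
}
manta_formats <- c(
  "##FORMAT=<ID=PR,Number=.,Type=Integer,Description=\"t\">",
  "##FORMAT=<ID=SR,Number=.,Type=Integer,Description=\"t\">")

test_that("symbolic deletions are normalized with footprints and support", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(manta_formats),
    paste("tg1", 1000, "DEL1", "N", "<DEL>", 60, "PASS",
          "SVTYPE=DEL;END=2000;CIPOS=-5,5;CIEND=-7,7",
          "PR:SR", "20,0:15,0", "12,9:10,8", sep = "\t")), path)
  svs <- read_sv_vcf(path, "manta")
  expect_equal(nrow(svs), 1)
  expect_equal(svs$sv_type, "DEL")
  expect_equal(svs$length, 1000)
  expect_equal(svs$ori1, "left")
  expect_equal(svs$ori2, "right")
  expect_equal(c(svs$fp1_start, svs$fp1_end), c(995, 1005))
  expect_equal(c(svs$fp2_start, svs$fp2_end), c(1993, 2007))
  # manta PR/SR are (ref,var) pairs; variant = 9+8, reference = 12+10
  expect_equal(svs$tumor_var, 17)
  expect_equal(svs$tumor_ref, 22)
  expect_equal(svs$tumor_af, 17 / 39)
  expect_equal(svs$normal_af, 0)
})

test_that("breakend mates join into one interchromosomal record", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(manta_formats),
    paste("tg1", 5000, "B1", "N", "N[tg2:7000[", 60, "PASS",
          "SVTYPE=BND;MATEID=B2;CIPOS=-10,10",
          "PR:SR", "30,0:22,0", "14,11:9,7", sep = "\t"),
    paste("tg2", 7000, "B2", "N", "]tg1:5000]N", 60, "PASS",
          "SVTYPE=BND;MATEID=B1;CIPOS=-10,10",
          "PR:SR", "30,0:22,0", "14,11:9,7", sep = "\t")), path)
  svs <- read_sv_vcf(path, "manta")
  expect_equal(nrow(svs), 1)
  expect_equal(svs$sv_type, "CTX")
  expect_true(is.na(svs$length))
  expect_equal(svs$ori1, "left")
  expect_equal(svs$ori2, "right")
})

test_that("unmatched mates are dropped with a warning", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(manta_formats),
    paste("tg1", 5000, "B1", "N", "N[tg2:7000[", 60, "PASS",
          "SVTYPE=BND;MATEID=BGONE", "PR:SR", "1,0:1,0", "1,1:1,1",
          sep = "\t")), path)
  expect_warning(svs <- read_sv_vcf(path, "manta"), "no mate")
  expect_equal(nrow(svs), 0)
})

test_that("breakend orientation pairs map onto SV types, symmetrically", {
  expect_equal(classify_sv_type("tg1", "left", "tg1", "right", 100, 900), "DEL")
  expect_equal(classify_sv_type("tg1", "right", "tg1", "left", 100, 900), "DUP")
  expect_equal(classify_sv_type("tg1", "left", "tg1", "left", 100, 900), "INV")
  expect_equal(classify_sv_type("tg1", "right", "tg1", "right", 100, 900), "INV")
  expect_equal(classify_sv_type("tg1", "left", "tg2", "right", 100, 900), "CTX")
  # invariant under swapping the breakends
  for (o1 in c("left", "right")) for (o2 in c("left", "right")) {
    expect_equal(
      classify_sv_type("tg1", o1, "tg1", o2, 100, 900),
      classify_sv_type("tg1", o2, "tg1", o1, 900, 100)
    )
  }
})

test_that("allele fractions from summed read evidence", {
  expect_equal(compute_af(10, 10), 0.5)
  expect_equal(compute_af(0, 25), 0)
  # paired-end (6) + split-read (4) variant evidence vs 15 reference
  expect_equal(compute_af(6 + 4, 15), 0.40)
  expect_true(is.na(compute_af(0, 0)))
  # monotone in variant reads at fixed depth
  depth <- 40
  afs <- compute_af(0:depth, depth - (0:depth))
  expect_true(all(diff(afs) > 0))
})

test_that("normalized SVs round-trip through a generic VCF", {
  svs <- rbind(
    make_sv("tg1", 1000, "left", "tg1", 2000, "right", id = "a", fp = 5L,
            tv = 12, tr = 30, nv = 2, nr = 28),
    make_sv("tg1", 5000, "right", "tg1", 9000, "left", id = "b",
            tv = 7, tr = 3, nv = 0, nr = 10),
    make_sv("tg1", 100, "left", "tg2", 300, "left", id = "c", fp = 10L,
            tv = 5, tr = 5, nv = 5, nr = 5)
  )
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(svs, path)
  back <- read_sv_vcf(path, "generic")
  back$id <- sub("_1$", "", back$id)
  back$caller <- svs$caller
  expect_equal(back[order(back$id), names(svs)],
               svs[order(svs$id), ], ignore_attr = TRUE)
})

test_that("all three caller dialects normalize to the same variants", {
  sc <- shared_cohort()
  pdir <- file.path(sc$dir, "patients", "P01")
  per_caller <- lapply(c("manta", "delly", "gridss"), function(cl) {
    svs <- read_sv_vcf(file.path(pdir, paste0(cl, ".vcf")), cl)
    svs <- svs[order(svs$chrom1, svs$pos1), ]
    rownames(svs) <- NULL
    svs
  })
  cols <- c("chrom1", "pos1", "ori1", "chrom2", "pos2", "ori2", "sv_type",
            "tumor_var", "tumor_ref", "normal_var", "normal_ref")
  expect_equal(per_caller[[1]][, cols], per_caller[[2]][, cols],
               ignore_attr = TRUE)
  expect_equal(per_caller[[1]][, cols], per_caller[[3]][, cols],
               ignore_attr = TRUE)
})

test_that("records failing FILTER are kept but flagged", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(manta_formats),
    paste("tg1", 1000, "DEL1", "N", "<DEL>", 60, "MinQual",
          "SVTYPE=DEL;END=2000", "PR:SR", "1,0:1,0", "1,1:1,1",
          sep = "\t")), path)
  svs <- read_sv_vcf(path, "manta")
  expect_equal(nrow(svs), 1)
  expect_false(svs$filter_pass)
  expect_equal(svs$filter_status, "MinQual")
})
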