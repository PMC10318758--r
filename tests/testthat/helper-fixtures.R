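# Shared fixtures, built in code at test time.

# One simulated cohort, resolved once and reused across test files.
.cohort_env <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.cohort_env$res)) {
    dir <- file.path(tempdir(), "fusesv-shared-cohort")
    .cohort_env$truth <- run_simulate(dir, seed = 101L)
    .cohort_env$res <- suppressWarnings(resolve_cohort_dir(dir))
    .cohort_env$dir <- dir
  }
  list(truth = .cohort_env$truth, res = .cohort_env$res, dir = .cohort_env$dir)
}

# Minimal two-gene annotation: G1 on + strand, G2 on - strand, exon
# boundaries chosen so intron arithmetic is easy to eyeball.
toy_gtf_lines <- function() {
  a <- function(...) {
    kv <- list(...)
    paste0(names(kv), " \"", unlist(kv), "\";", collapse = " ")
  }
  c(
    paste("tg1", "toy", "gene", 100, 5200, ".", "+", ".",
          a(gene_id = "G1", gene_name = "ALPHA", gene_type = "protein_coding"),
          sep = "\t"),
    paste("tg1", "toy", "transcript", 100, 5200, ".", "+", ".",
          paste(a(gene_id = "G1", transcript_id = "T1", gene_name = "ALPHA",
                  gene_type = "protein_coding",
                  transcript_type = "protein_coding",
                  transcript_support_level = 1),
                'tag "basic"; tag "CCDS"; tag "MANE_Select";'),
          sep = "\t"),
    paste("tg1", "toy", "exon", 100, 200, ".", "+", ".",
          a(gene_id = "G1", transcript_id = "T1", exon_number = 1), sep = "\t"),
    paste("tg1", "toy", "exon", 500, 1000, ".", "+", ".",
          a(gene_id = "G1", transcript_id = "T1", exon_number = 2), sep = "\t"),
    paste("tg1", "toy", "exon", 5000, 5200, ".", "+", ".",
          a(gene_id = "G1", transcript_id = "T1", exon_number = 3), sep = "\t"),
    paste("tg1", "toy", "gene", 40000, 58000, ".", "-", ".",
          a(gene_id = "G2", gene_name = "BRAVO", gene_type = "protein_coding"),
          sep = "\t"),
    paste("tg1", "toy", "transcript", 40000, 58000, ".", "-", ".",
          paste(a(gene_id = "G2", transcript_id = "T2", gene_name = "BRAVO",
                  gene_type = "protein_coding",
                  transcript_type = "protein_coding",
                  transcript_support_level = 1),
                'tag "basic"; tag "CCDS"; tag "MANE_Select";'),
          sep = "\t"),
    paste("tg1", "toy", "exon", 40000, 40200, ".", "-", ".",
          a(gene_id = "G2", transcript_id = "T2", exon_number = 3), sep = "\t"),
    paste("tg1", "toy", "exon", 50000, 50300, ".", "-", ".",
          a(gene_id = "G2", transcript_id = "T2", exon_number = 2), sep = "\t"),
    paste("tg1", "toy", "exon", 57800, 58000, ".", "-", ".",
          a(gene_id = "G2", transcript_id = "T2", exon_number = 1), sep = "\t")
  )
}

toy_model <- function() {
  path <- tempfile(fileext = ".gtf")
  writeLines(toy_gtf_lines(), path)
  parse_gtf(path)
}

# A transcript table in the GeneModel layout, for select_canonical tests.
make_tx <- function(id, tags = character(0), biotype = "protein_coding",
                    tsl = 1L, cds = 900L) {
  df <- data.frame(transcript_id = id, gene_id = "G", gene_name = "G",
                   chrom = "tg1", strand = "+", tx_start = 1L, tx_end = 10L,
                   biotype = biotype, tsl = tsl, stringsAsFactors = FALSE)
  df$tags <- list(tags)
  df$cds_length <- cds
  df
}

# Merged-prediction row in the merge_predictions() layout.
make_prediction <- function(gene5, gene3, pos5, pos3, strand5 = "+",
                            strand3 = "+", chrom5 = "tg1", chrom3 = "tg1",
                            both = TRUE, ffpm = 1) {
  pred <- data.frame(
    gene5_id = gene5, gene3_id = gene3, gene5_name = gene5,
    gene3_name = gene3, predicted_by_both = both,
    callers = if (both) "fusioncatcher,star_fusion" else "star_fusion",
    max_ffpm = ffpm, low_expression = ffpm < 0.1, healthy_flag = FALSE,
    stringsAsFactors = FALSE
  )
  pred$breakpoints <- list(data.frame(
    caller = "star_fusion", chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
    chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
    junction_reads = 5L, spanning_fragments = 5L, ffpm = ffpm,
    stringsAsFactors = FALSE
  ))
  pred
}

# Normalized SV row in the read_sv_vcf() layout.
make_sv <- function(chrom1, pos1, ori1, chrom2, pos2, ori2,
                    caller = "manta", id = "sv1", fp = 0L,
                    tv = 20L, tr = 20L, nv = 0L, nr = 40L,
                    filter = "PASS") {
  sv_type <- classify_sv_type(chrom1, ori1, chrom2, ori2, pos1, pos2)
  data.frame(
    caller = caller, id = id, chrom1 = chrom1, pos1 = pos1, ori1 = ori1,
    fp1_start = pos1 - fp, fp1_end = pos1 + fp,
    chrom2 = chrom2, pos2 = pos2, ori2 = ori2,
    fp2_start = pos2 - fp, fp2_end = pos2 + fp,
    sv_type = sv_type,
    length = if (sv_type == "CTX") NA_integer_ else abs(pos2 - pos1),
    tumor_var = tv, tumor_ref = tr, normal_var = nv, normal_ref = nr,
    tumor_af = compute_af(tv, tr), normal_af = compute_af(nv, nr),
    filter_status = filter, filter_pass = filter == "PASS",
    stringsAsFactors = FALSE
  )
}

# Brute-force matcher: all-pairs scan over SVs x interval levels with
# plain arithmetic, independent of the GRanges overlap index.
brute_force_supports <- function(prediction, model, svs, cfg = fusion_config()) {
  bps <- prediction$breakpoints[[1]]
  hits <- list()
  for (b in seq_len(nrow(bps))) {
    mis5 <- derive_matching_intervals(model, prediction$gene5_id,
                                      bps$pos5[b], "five_prime", cfg)
    mis3 <- derive_matching_intervals(model, prediction$gene3_id,
                                      bps$pos3[b], "three_prime", cfg)
    if (!length(mis5$levels) || !length(mis3$levels)) next
    lv5 <- as.data.frame(mis5$levels)
    lv3 <- as.data.frame(mis3$levels)
    for (s in seq_len(nrow(svs))) {
      ends <- list(
        list(chrom = svs$chrom1[s], lo = svs$fp1_start[s],
             hi = svs$fp1_end[s], pos = svs$pos1[s], ori = svs$ori1[s]),
        list(chrom = svs$chrom2[s], lo = svs$fp2_start[s],
             hi = svs$fp2_end[s], pos = svs$pos2[s], ori = svs$ori2[s])
      )
      level_of <- function(e, lv, mis) {
        if (e$ori != mis$expected_orientation) return(NULL)
        for (r in seq_len(nrow(lv))) {
          if (as.character(lv$seqnames[r]) == e$chrom &&
              e$hi >= lv$start[r] && e$lo <= lv$end[r]) {
            return(lv$level[r])
          }
        }
        NULL
      }
      for (assign in list(c(1, 2), c(2, 1))) {
        l5 <- level_of(ends[[assign[1]]], lv5, mis5)
        l3 <- level_of(ends[[assign[2]]], lv3, mis3)
        if (!is.null(l5) && !is.null(l3)) {
          key <- svs$id[s]
          cand <- list(sv_id = key, level5 = l5, level3 = l3,
                       dist5 = abs(ends[[assign[1]]]$pos - mis5$rna_breakpoint),
                       dist3 = abs(ends[[assign[2]]]$pos - mis3$rna_breakpoint))
          rank <- function(x) {
            match(x, c("intron_exact", "fixed_window", "gene_body", "gene_flank"))
          }
          if (is.null(hits[[key]]) ||
              rank(cand$level5) + rank(cand$level3) <
                rank(hits[[key]]$level5) + rank(hits[[key]]$level3) ||
              (rank(cand$level5) + rank(cand$level3) ==
                 rank(hits[[key]]$level5) + rank(hits[[key]]$level3) &&
               cand$dist5 + cand$dist3 <
                 hits[[key]]$dist5 + hits[[key]]$dist3)) {
            hits[[key]] <- cand
          }
        }
      }
    }
  }
  hits
}

# setequal on possibly-empty character sets
expect_same_ids <- function(got, want) {
  got <- as.character(got)
  want <- if (is.null(want)) character(0) else as.character(want)
  expect_equal(sort(unique(got)), sort(unique(want)))
}

# Exact two-sided rank-sum p-value by complete enumeration (n <= 12),
# matching the R convention of doubling the smaller tail.
exact_ranksum_p <- function(x, y) {
  all <- c(x, y)
  stopifnot(length(all) <= 12, !anyDuplicated(all))
  r <- rank(all)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(all), m)
  w_null <- apply(combos, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  p_low <- mean(w_null <= w_obs)
  p_high <- mean(w_null >= w_obs)
  min(1, 2 * min(p_low, p_high))
}
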