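#' Configuration of the toy genome generator
#'
#' The toy genome uses invented contig names (`tg1`, `tg2`, ...) so that
#' nothing can silently depend on a real reference. Intron lengths are a
#' mixture of short introns and, with probability `long_intron_prob`,
#' long introns well above 10 kb -- the regime where fixed-size matching
#' windows around an RNA breakpoint fail and gene-structure-derived
#' intervals are required.
#'
#' @param n_genes Number of genes. Default 150.
#' @param genes_per_contig Genes laid head-to-tail per contig. Default 6.
#' @param n_exons_range Min/max exons per gene. Default c(4, 8).
#' @param exon_len_range Exon length range (bp). Default c(80, 300).
#' @param intron_len_range Short-intron length range (bp). Default
#'   c(300, 5000).
#' @param long_intron_prob Probability that an intron is drawn from the
#'   long regime instead. Default 0.2.
#' @param long_intron_len_range Long-intron length range (bp). Default
#'   c(14000, 40000).
#' @param intergenic_range Gap between consecutive genes (bp); kept above
#'   twice the default matching flank so neighboring genes never share
#'   flank intervals. Default c(25000, 60000).
#' @return Named list.
#' @export
toy_genome_config <- function(n_genes = 150L,
                              genes_per_contig = 6L,
                              n_exons_range = c(4L, 8L),
                              exon_len_range = c(80L, 300L),
                              intron_len_range = c(300L, 5000L),
                              long_intron_prob = 0.2,
                              long_intron_len_range = c(14000L, 40000L),
                              intergenic_range = c(25000L, 60000L)) {
  list(n_genes = as.integer(n_genes),
       genes_per_contig = as.integer(genes_per_contig),
       n_exons_range = as.integer(n_exons_range),
       exon_len_range = as.integer(exon_len_range),
       intron_len_range = as.integer(intron_len_range),
       long_intron_prob = long_intron_prob,
       long_intron_len_range = as.integer(long_intron_len_range),
       intergenic_range = as.integer(intergenic_range))
}

#' Generate a seeded toy genome with Gencode-dialect annotation
#'
#' Deterministic for a given seed: re-running produces a byte-identical
#' GTF. Each gene gets a primary transcript covering all exons plus, for
#' most genes, an alternate transcript engineered to lose the canonical-
#' transcript selection at a specific step (missing MANE tag, missing
#' CCDS, missing APPRIS principal tag, non-coding biotype, worse
#' transcript support level, shorter CDS, or a pure id tie) so every
#' branch of the stepwise filter is exercised while the primary
#' transcript is always the canonical choice.
#'
#' @param out_gtf Path of the GTF file to write.
#' @param cfg A [toy_genome_config()].
#' @param seed Integer seed.
#' @return A `ToyGenome` list: `genes` (data.frame incl. per-gene long
#'   intron bookkeeping), `transcripts`, `exons` (named list of
#'   data.frames with genomic `start`/`end`), `gtf_path`, `contigs`.
#' @export
generate_toy_genome <- function(out_gtf, cfg = toy_genome_config(), seed = 1L) {
  set.seed(seed)
  if (cfg$intergenic_range[1] <= 0) stop("infeasible config: intergenic gap must be positive")

  genes <- list()
  tx_rows <- list()
  exons <- list()
  gtf <- character(0)

  cursor <- stats::setNames(
    rep(50000L, ceiling(cfg$n_genes / cfg$genes_per_contig)),
    paste0("tg", seq_len(ceiling(cfg$n_genes / cfg$genes_per_contig)))
  )

  attr_str <- function(...) {
    kv <- list(...)
    paste0(paste0(names(kv), " \"", unlist(kv), "\";", collapse = " "))
  }

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("G%03d", g)
    gene_name <- sprintf("GN%03d", g)
    contig <- paste0("tg", (g - 1) %/% cfg$genes_per_contig + 1)
    strand <- if (stats::runif(1) < 0.5) "+" else "-"

    n_ex <- sample(cfg$n_exons_range[1]:cfg$n_exons_range[2], 1)
    ex_len <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], n_ex,
                     replace = TRUE)
    long <- stats::runif(n_ex - 1) < cfg$long_intron_prob
    in_len <- ifelse(long,
      sample(cfg$long_intron_len_range[1]:cfg$long_intron_len_range[2],
             n_ex - 1, replace = TRUE),
      sample(cfg$intron_len_range[1]:cfg$intron_len_range[2],
             n_ex - 1, replace = TRUE))

    start <- cursor[[contig]]
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    p <- start
    for (i in seq_len(n_ex)) {
      ex_start[i] <- p
      ex_end[i] <- p + ex_len[i] - 1L
      if (i < n_ex) p <- ex_end[i] + in_len[i] + 1L
    }
    gene_start <- ex_start[1]; gene_end <- ex_end[n_ex]
    cursor[[contig]] <- gene_end +
      sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1)

    branch <- (g - 1) %% 7 + 1  # which selection step the alternate loses at
    primary_id <- paste0("T", gene_id, ".1")
    alt_id <- paste0("T", gene_id, ".2")

    primary <- list(id = primary_id, ex_start = ex_start, ex_end = ex_end,
                    biotype = "protein_coding", tsl = 1L,
                    tags = c("basic", "CCDS", "appris_principal_1"),
                    coding = TRUE)
    alt <- NULL
    if (branch == 1) {                       # alternate lacks MANE
      primary$tags <- c(primary$tags, "MANE_Select")
      alt <- primary; alt$id <- alt_id
      alt$tags <- setdiff(alt$tags, "MANE_Select")
    } else if (branch == 2) {                # alternate lacks basic
      alt <- primary; alt$id <- alt_id
      alt$tags <- setdiff(alt$tags, "basic")
    } else if (branch == 3) {                # alternate lacks CCDS
      alt <- primary; alt$id <- alt_id
      alt$tags <- setdiff(alt$tags, "CCDS")
    } else if (branch == 4) {                # alternate lacks APPRIS
      alt <- primary; alt$id <- alt_id
      alt$tags <- setdiff(alt$tags, "appris_principal_1")
    } else if (branch == 5) {                # alternate is non-coding
      alt <- primary; alt$id <- alt_id
      alt$biotype <- "lncRNA"; alt$coding <- FALSE
    } else if (branch == 6) {                # alternate has worse TSL
      alt <- primary; alt$id <- alt_id
      alt$tsl <- 3L
    } else {                                 # alternate has shorter CDS
      alt <- primary; alt$id <- alt_id
      alt$ex_start <- ex_start[-n_ex]; alt$ex_end <- ex_end[-n_ex]
    }
    # every third gene: single-transcript gene instead
    if (g %% 3 == 0) alt <- NULL

    tx_list <- c(list(primary), if (!is.null(alt)) list(alt))

    gtf <- c(gtf, paste(contig, "toysim", "gene", gene_start, gene_end,
                        ".", strand, ".",
                        attr_str(gene_id = gene_id, gene_name = gene_name,
                                 gene_type = "protein_coding"),
                        sep = "\t"))
    for (tx in tx_list) {
      n <- length(tx$ex_start)
      tagattrs <- paste0(" ", paste0("tag \"", tx$tags, "\";", collapse = " "))
      gtf <- c(gtf, paste(contig, "toysim", "transcript",
                          tx$ex_start[1], tx$ex_end[n], ".", strand, ".",
                          paste0(attr_str(gene_id = gene_id,
                                          transcript_id = tx$id,
                                          gene_name = gene_name,
                                          gene_type = "protein_coding",
                                          transcript_type = tx$biotype,
                                          transcript_support_level = tx$tsl),
                                 tagattrs),
                          sep = "\t"))
      for (i in seq_len(n)) {
        gtf <- c(gtf, paste(contig, "toysim", "exon",
                            tx$ex_start[i], tx$ex_end[i], ".", strand, ".",
                            attr_str(gene_id = gene_id, transcript_id = tx$id,
                                     exon_number = i),
                            sep = "\t"))
      }
      if (tx$coding) {
        # CDS: exon structure trimmed by 30 bp at each transcript end
        cs <- tx$ex_start; ce <- tx$ex_end
        if (strand == "+") {
          cs[1] <- min(cs[1] + 30L, ce[1]); ce[n] <- max(ce[n] - 30L, cs[n])
        } else {
          ce[n] <- max(ce[n] - 30L, cs[n]); cs[1] <- min(cs[1] + 30L, ce[1])
        }
        for (i in seq_len(n)) {
          gtf <- c(gtf, paste(contig, "toysim", "CDS", cs[i], ce[i],
                              ".", strand, "0",
                              attr_str(gene_id = gene_id,
                                       transcript_id = tx$id),
                              sep = "\t"))
        }
      }
      exons[[tx$id]] <- data.frame(start = tx$ex_start, end = tx$ex_end)
      tx_rows[[tx$id]] <- data.frame(
        transcript_id = tx$id, gene_id = gene_id, biotype = tx$biotype,
        tsl = tx$tsl, n_exons = n, stringsAsFactors = FALSE
      )
    }

    # transcript-orientation indices of introns longer than 12 kb
    tx_intron_len <- if (strand == "+") in_len else rev(in_len)
    genes[[gene_id]] <- data.frame(
      gene_id = gene_id, gene_name = gene_name, contig = contig,
      strand = strand, start = gene_start, end = gene_end,
      primary_tx = primary_id, n_exons = n_ex,
      long_introns_tx = paste(which(tx_intron_len > 12000L), collapse = ","),
      stringsAsFactors = FALSE
    )
  }

  writeLines(gtf, out_gtf)
  structure(
    list(genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
         transcripts = do.call(rbind, c(tx_rows, list(make.row.names = FALSE))),
         exons = exons, gtf_path = out_gtf, contigs = names(cursor)),
    class = "ToyGenome"
  )
}

#' Configuration of the synthetic cohort generator
#'
#' The event mix emulates the categories observed when integrating RNA
#' fusion predictions with WGS SVs in a tumor/normal cohort:
#' tumor-specific fusions with a genuine underlying SV (some lowly
#' expressed, some with DNA breakends far into long introns), chimeric
#' transcripts caused by germline SVs, low-allele-fraction events in
#' amplified regions, read-through chimera without any SV, single-caller
#' RNA false positives, and common population SVs with no transcript
#' consequence.
#'
#' @param n_patients Cohort size. Default 20.
#' @param n_true_fusion,n_germline,n_low_af,n_readthrough,n_false_positive,n_population_sv
#'   Event counts per kind. Defaults 24, 8, 6, 8, 10, 4 (60 events).
#' @param n_long_offset How many true fusions place a DNA breakend more
#'   than 10 kb from the RNA breakpoint inside a long intron. Default 4.
#' @param n_single_caller How many true fusions are reported by only one
#'   SV caller (these must fail the high-confidence rule). Default 4.
#' @param low_ffpm_values FFPM values planted on dedicated lowly
#'   expressed true fusions (all below the conventional 0.1 cutoff).
#'   Default c(0.03, 0.07, 0.08, 0.09).
#' @param jitter_sd Per-caller breakpoint jitter standard deviation (bp).
#'   Default 0 (noise-free study condition).
#' @param footprint_halfwidth Named per-caller breakend footprint
#'   half-widths (bp).
#' @param broad_footprint_halfwidths Occasional broad assembly footprints
#'   assigned to designated events (bp).
#' @param ctx_fraction Fraction of SV-backed events placed across two
#'   contigs as translocations. Default 0.3.
#' @param total_fragments RNA library size used to convert FFPM to read
#'   counts. Default 1e8.
#' @return Named list.
#' @export
cohort_config <- function(n_patients = 20L,
                          n_true_fusion = 24L,
                          n_germline = 8L,
                          n_low_af = 6L,
                          n_readthrough = 8L,
                          n_false_positive = 10L,
                          n_population_sv = 4L,
                          n_long_offset = 4L,
                          n_single_caller = 4L,
                          low_ffpm_values = c(0.03, 0.07, 0.08, 0.09),
                          jitter_sd = 0,
                          footprint_halfwidth = c(manta = 5L, delly = 15L, gridss = 0L),
                          broad_footprint_halfwidths = c(400L, 1100L),
                          ctx_fraction = 0.3,
                          total_fragments = 1e8) {
  list(n_patients = as.integer(n_patients),
       n_true_fusion = as.integer(n_true_fusion),
       n_germline = as.integer(n_germline),
       n_low_af = as.integer(n_low_af),
       n_readthrough = as.integer(n_readthrough),
       n_false_positive = as.integer(n_false_positive),
       n_population_sv = as.integer(n_population_sv),
       n_long_offset = as.integer(n_long_offset),
       n_single_caller = as.integer(n_single_caller),
       low_ffpm_values = low_ffpm_values,
       jitter_sd = jitter_sd,
       footprint_halfwidth = footprint_halfwidth,
       broad_footprint_halfwidths = as.integer(broad_footprint_halfwidths),
       ctx_fraction = ctx_fraction,
       total_fragments = total_fragments)
}

# --- internal planting helpers -------------------------------------------

# exon table of a gene's primary transcript plus orientation helpers
gene_struct <- function(genome, gene_id) {
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  ex <- genome$exons[[g$primary_tx]]
  list(g = g, ex = ex, n = nrow(ex), strand = g$strand, contig = g$contig)
}

# Breakpoint/breakend plan for one fusion side.
# side "five_prime": RNA breakpoint at transcript-orientation end of exon
# j (tx orientation, 1..n-1), DNA breakend `offset` bp into the following
# intron. side "three_prime": RNA breakpoint at transcript-orientation
# start of exon k (2..n), DNA breakend `offset` bp into the preceding
# intron.
plan_side <- function(gs, side, tx_exon, offset) {
  n <- gs$n; st <- gs$strand
  gidx <- if (st == "+") tx_exon else n - tx_exon + 1L
  if (side == "five_prime") {
    rna <- if (st == "+") gs$ex$end[gidx] else gs$ex$start[gidx]
    dna <- if (st == "+") rna + offset else rna - offset
    ori <- if (st == "+") "left" else "right"
  } else {
    rna <- if (st == "+") gs$ex$start[gidx] else gs$ex$end[gidx]
    dna <- if (st == "+") rna - offset else rna + offset
    ori <- if (st == "+") "right" else "left"
  }
  list(rna = rna, dna = dna, ori = ori, chrom = gs$contig, strand = st)
}

# length of the intron adjacent to the planned breakpoint, tx orientation
intron_len_at <- function(gs, side, tx_exon) {
  n <- gs$n; st <- gs$strand
  gidx <- if (st == "+") tx_exon else n - tx_exon + 1L
  if (side == "five_prime") {
    if (st == "+") gs$ex$start[gidx + 1] - gs$ex$end[gidx] - 1L
    else gs$ex$start[gidx] - gs$ex$end[gidx - 1] - 1L
  } else {
    if (st == "+") gs$ex$start[gidx] - gs$ex$end[gidx - 1] - 1L
    else gs$ex$start[gidx + 1] - gs$ex$end[gidx] - 1L
  }
}

# Derive the SV type implied by two planted oriented breakends (ground
# truth definition; the reader re-derives it from VCF records).
planted_sv_type <- function(chrom5, pos5, ori5, chrom3, pos3, ori3) {
  if (chrom5 != chrom3) return("CTX")
  lo_ori <- if (pos5 <= pos3) ori5 else ori3
  hi_ori <- if (pos5 <= pos3) ori3 else ori5
  if (lo_ori == hi_ori) "INV" else if (lo_ori == "left") "DEL" else "DUP"
}

#' Plant a synthetic cohort with a machine-readable truth manifest
#'
#' Writes, per patient, fusion prediction tables in both RNA-caller
#' dialects and SV VCFs in all three WGS-caller dialects; cohort-level
#' expression/copy-number/FGA tables; plain-table annotation resources
#' (healthy and cancer chimera pairs, population SVs, repeats, segmental
#' duplications, cancer-gene lists); and `truth.tsv`, the manifest every
#' emitted record traces back to. Deterministic for a given seed.
#'
#' Every planted fusion has RNA breakpoints exactly at exon boundaries of
#' the gene's canonical transcript and DNA breakends inside the adjacent
#' introns with orientations consistent with the chimeric transcript.
#' Read-through chimera receive RNA rows in both dialects but no SV, and
#' live on contigs that carry no SVs at all. RNA-only false positives are
#' reported by a single RNA caller. Population SVs appear in all three
#' VCFs in intergenic space.
#'
#' @param genome A `ToyGenome` from [generate_toy_genome()].
#' @param out_dir Output directory (created if needed).
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @return The truth manifest data.frame (also written to
#'   `<out_dir>/truth.tsv`), with attributes `paths` (named list of all
#'   emitted files) and `expected` (per-patient expected high-confidence
#'   fusion counts and planted FGA).
#' @export
plant_cohort <- function(genome, out_dir, cfg = cohort_config(), seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "resources"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "expression"), showWarnings = FALSE)

  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  for (p in patients) {
    dir.create(file.path(out_dir, "patients", p), recursive = TRUE,
               showWarnings = FALSE)
  }

  n_contigs <- length(genome$contigs)
  if (n_contigs < 10) stop("toy genome too small for the cohort layout")
  rt_contigs <- genome$contigs[(n_contigs - 7):(n_contigs - 4)]
  fp_contigs <- genome$contigs[(n_contigs - 3):n_contigs]
  sv_contigs <- setdiff(genome$contigs, c(rt_contigs, fp_contigs))

  # pool of genes available for SV-backed events; a gene is consumed when
  # drawn, so no gene serves two events and all pairs are unique
  pool <- genome$genes[genome$genes$contig %in% sv_contigs &
                         genome$genes$n_exons >= 3, ]
  pool <- pool[sample(nrow(pool)), ]
  take_gene <- function(pred = NULL) {
    i <- if (is.null(pred)) 1L else which(pred(pool))[1]
    if (is.na(i) || nrow(pool) == 0) {
      stop("gene pool exhausted; enlarge the toy genome or reduce events")
    }
    g <- pool[i, ]
    pool <<- pool[-i, , drop = FALSE]
    g
  }

  # --- patient assignment per event kind (burden structure is part of
  # the study design: three high-burden patients, the rest sparse).
  # Indices wrap around for cohorts smaller than the default layout.
  pat <- function(i) patients[(i - 1L) %% cfg$n_patients + 1L]
  assign_true <- pat(c(rep(1L, 6), rep(2L, 6), rep(3L, 5),
                       4:10)[seq_len(cfg$n_true_fusion)])
  assign_germline <- pat((seq_len(cfg$n_germline) - 1L) %% 8L + 4L)
  assign_low_af <- pat((seq_len(cfg$n_low_af) - 1L) %% 6L + 11L)
  assign_rt <- pat((seq_len(cfg$n_readthrough) - 1L) %% 8L + 13L)
  assign_fp <- pat((seq_len(cfg$n_false_positive) - 1L) %% 10L + 1L)
  assign_pop <- pat((seq_len(cfg$n_population_sv) - 1L) %% 4L + 17L)
  if (cfg$n_germline < 2) stop("cohort needs at least two germline events")

  # designated special true fusions (indices into the true-fusion list):
  # long-offset events inside the first high-burden block, lowly
  # expressed events inside the third, single-caller events on the
  # singleton patients -- the three groups never overlap
  long_idx <- seq_len(cfg$n_long_offset)
  low_ffpm_idx <- 13L + seq_along(cfg$low_ffpm_values)
  singles <- which(assign_true %in% sprintf("P%02d", 4:7))[seq_len(cfg$n_single_caller)]

  callers <- c("manta", "delly", "gridss")
  truth <- list()
  sv_records <- stats::setNames(
    rep(list(stats::setNames(vector("list", length(callers)), callers)),
        cfg$n_patients), patients)
  rna_rows <- stats::setNames(rep(list(list(sf = list(), fc = list())),
                                  cfg$n_patients), patients)
  eid <- 0L

  plant_sv_event <- function(kind, patient, long_offset = FALSE,
                             single_caller = FALSE, ffpm = NULL,
                             force_intra = FALSE) {
    eid <<- eid + 1L
    want_ctx <- !force_intra && !long_offset && stats::runif(1) < cfg$ctx_fraction
    if (want_ctx) {
      g5 <- take_gene()
      g3 <- take_gene(function(p) p$contig != g5$contig)
    } else {
      # intra-contig pair: the 5' gene must come from a contig that still
      # holds a partner (and a long intron when required)
      paired <- names(which(table(pool$contig) >= 2))
      g5 <- take_gene(function(p) {
        p$contig %in% paired & (!long_offset | nzchar(p$long_introns_tx))
      })
      g3 <- take_gene(function(p) p$contig == g5$contig)
    }
    gs5 <- gene_struct(genome, g5$gene_id)
    gs3 <- gene_struct(genome, g3$gene_id)

    if (long_offset) {
      cand <- as.integer(strsplit(g5$long_introns_tx, ",")[[1]])
      cand <- cand[cand < gs5$n]
      j <- cand[sample.int(length(cand), 1)]
      len5 <- intron_len_at(gs5, "five_prime", j)
      d5 <- sample(12000:min(len5 - 20L, 30000L), 1)
    } else {
      j <- sample(seq_len(gs5$n - 1L), 1)
      len5 <- intron_len_at(gs5, "five_prime", j)
      d5 <- sample(20:max(21L, len5 - 20L), 1)
    }
    k <- sample(2:gs3$n, 1)
    len3 <- intron_len_at(gs3, "three_prime", k)
    d3 <- sample(20:max(21L, len3 - 20L), 1)

    s5 <- plan_side(gs5, "five_prime", j, d5)
    s3 <- plan_side(gs3, "three_prime", k, d3)
    sv_type <- planted_sv_type(s5$chrom, s5$dna, s5$ori, s3$chrom, s3$dna, s3$ori)

    support <- switch(kind,
      true_fusion = list(tv = sample(18:40, 1), tr = sample(18:40, 1),
                         nv = 0L, nr = sample(30:60, 1)),
      germline_sv_fusion = list(tv = sample(18:40, 1), tr = sample(18:40, 1),
                                nv = sample(18:40, 1), nr = sample(18:40, 1)),
      low_af_amplicon_fusion = list(tv = sample(6:10, 1),
                                    tr = sample(160:240, 1),
                                    nv = 0L, nr = sample(40:70, 1))
    )
    ev_callers <- if (single_caller) sample(callers, 1) else callers
    if (is.null(ffpm)) ffpm <- round(stats::runif(1, 0.12, 5), 2)

    taf <- support$tv / (support$tv + support$tr)
    naf <- if (support$nv + support$nr > 0) {
      support$nv / (support$nv + support$nr)
    } else NA_real_
    expected_class <- if (!is.na(naf) && naf >= 0.10) "germline"
      else if (taf >= 0.10) "tumor_specific" else "low_af"

    ev <- data.frame(
      event_id = sprintf("E%03d", eid), patient_id = patient, kind = kind,
      gene5_id = g5$gene_id, gene5_name = g5$gene_name,
      gene3_id = g3$gene_id, gene3_name = g3$gene_name,
      chrom5 = s5$chrom, rna_bp5 = s5$rna, strand5 = s5$strand,
      chrom3 = s3$chrom, rna_bp3 = s3$rna, strand3 = s3$strand,
      sv_pos5 = s5$dna, ori5 = s5$ori, sv_pos3 = s3$dna, ori3 = s3$ori,
      sv_type = sv_type, d5 = d5, d3 = d3,
      callers = paste(ev_callers, collapse = ","),
      ffpm = ffpm,
      tumor_var = support$tv, tumor_ref = support$tr,
      normal_var = support$nv, normal_ref = support$nr,
      expected_class = expected_class,
      expected_high_confidence = length(ev_callers) >= 2,
      expected_level = "intron_exact",
      long_offset = long_offset,
      stringsAsFactors = FALSE
    )
    truth[[length(truth) + 1L]] <<- ev

    for (cl in ev_callers) {
      sv_records[[patient]][[cl]][[length(sv_records[[patient]][[cl]]) + 1L]] <<-
        list(ev = ev, caller = cl)
    }
    add_rna_rows(patient, ev, both = TRUE)
    ev
  }

  add_rna_rows <- function(patient, ev, both = TRUE, which_caller = "sf",
                           annots = ".") {
    supporting <- as.integer(round(ev$ffpm * cfg$total_fragments / 1e6))
    junction <- supporting %/% 2L
    spanning <- supporting - junction
    if (both || which_caller == "sf") {
      rna_rows[[patient]]$sf[[length(rna_rows[[patient]]$sf) + 1L]] <<- data.frame(
        fusion = paste0(ev$gene5_name, "--", ev$gene3_name),
        junction = junction, spanning = spanning,
        left_gene = paste0(ev$gene5_name, "^", ev$gene5_id),
        left_bp = paste(ev$chrom5, ev$rna_bp5, ev$strand5, sep = ":"),
        right_gene = paste0(ev$gene3_name, "^", ev$gene3_id),
        right_bp = paste(ev$chrom3, ev$rna_bp3, ev$strand3, sep = ":"),
        ffpm = ev$ffpm, annots = annots, stringsAsFactors = FALSE
      )
    }
    if (both || which_caller == "fc") {
      rna_rows[[patient]]$fc[[length(rna_rows[[patient]]$fc) + 1L]] <<- data.frame(
        g5 = ev$gene5_name, g3 = ev$gene3_name,
        g5id = ev$gene5_id, g3id = ev$gene3_id,
        bp5 = paste(ev$chrom5, ev$rna_bp5, ev$strand5, sep = ":"),
        bp3 = paste(ev$chrom3, ev$rna_bp3, ev$strand3, sep = ":"),
        spanning = spanning, junction = junction,
        desc = if (grepl("healthy", annots)) "healthy,readthrough" else ".",
        stringsAsFactors = FALSE
      )
    }
  }

  # --- plant all events -------------------------------------------------
  true_events <- list()
  for (i in seq_len(cfg$n_true_fusion)) {
    true_events[[i]] <- plant_sv_event(
      "true_fusion", assign_true[i],
      long_offset = i %in% long_idx,
      single_caller = i %in% singles,
      ffpm = if (i %in% low_ffpm_idx) {
        cfg$low_ffpm_values[match(i, low_ffpm_idx)]
      } else NULL
    )
  }
  germline_events <- list()
  for (i in seq_len(cfg$n_germline)) {
    germline_events[[i]] <- plant_sv_event(
      "germline_sv_fusion", assign_germline[i],
      force_intra = i <= 2  # events 1-2 need spans for population-SV rows
    )
  }
  low_af_events <- list()
  for (i in seq_len(cfg$n_low_af)) {
    low_af_events[[i]] <- plant_sv_event("low_af_amplicon_fusion",
                                         assign_low_af[i])
  }

  # read-through chimera: adjacent genes on SV-free contigs, no SV
  rt_genes <- genome$genes[genome$genes$contig %in% rt_contigs, ]
  rt_events <- list()
  for (i in seq_len(cfg$n_readthrough)) {
    contig <- rt_contigs[(i - 1) %% length(rt_contigs) + 1]
    on_contig <- rt_genes[rt_genes$contig == contig, ]
    slot <- (i - 1) %/% length(rt_contigs)
    g5 <- on_contig[2 * slot + 1, ]; g3 <- on_contig[2 * slot + 2, ]
    eid <- eid + 1L
    gs5 <- gene_struct(genome, g5$gene_id)
    gs3 <- gene_struct(genome, g3$gene_id)
    s5 <- plan_side(gs5, "five_prime", gs5$n - 1L, 0L)
    s3 <- plan_side(gs3, "three_prime", 2L, 0L)
    ev <- data.frame(
      event_id = sprintf("E%03d", eid), patient_id = assign_rt[i],
      kind = "readthrough_chimera",
      gene5_id = g5$gene_id, gene5_name = g5$gene_name,
      gene3_id = g3$gene_id, gene3_name = g3$gene_name,
      chrom5 = s5$chrom, rna_bp5 = s5$rna, strand5 = s5$strand,
      chrom3 = s3$chrom, rna_bp3 = s3$rna, strand3 = s3$strand,
      sv_pos5 = NA_integer_, ori5 = NA_character_,
      sv_pos3 = NA_integer_, ori3 = NA_character_,
      sv_type = NA_character_, d5 = NA_integer_, d3 = NA_integer_,
      callers = "", ffpm = round(stats::runif(1, 0.2, 2), 2),
      tumor_var = NA_integer_, tumor_ref = NA_integer_,
      normal_var = NA_integer_, normal_ref = NA_integer_,
      expected_class = NA_character_, expected_high_confidence = FALSE,
      expected_level = NA_character_, long_offset = FALSE,
      stringsAsFactors = FALSE
    )
    truth[[length(truth) + 1L]] <- ev
    add_rna_rows(assign_rt[i], ev, both = TRUE,
                 annots = if (i <= 4) "GTEx_recurrent,healthy" else ".")
    rt_events[[i]] <- ev
  }

  # RNA-only false positives: one caller each, SV-free contigs
  fp_genes <- genome$genes[genome$genes$contig %in% fp_contigs, ]
  fp_genes <- fp_genes[sample(nrow(fp_genes)), ]
  for (i in seq_len(cfg$n_false_positive)) {
    g5 <- fp_genes[2 * i - 1, ]; g3 <- fp_genes[2 * i, ]
    eid <- eid + 1L
    gs5 <- gene_struct(genome, g5$gene_id)
    gs3 <- gene_struct(genome, g3$gene_id)
    s5 <- plan_side(gs5, "five_prime", sample(seq_len(gs5$n - 1L), 1), 0L)
    s3 <- plan_side(gs3, "three_prime", sample(2:gs3$n, 1), 0L)
    ev <- data.frame(
      event_id = sprintf("E%03d", eid), patient_id = assign_fp[i],
      kind = "false_positive_rna",
      gene5_id = g5$gene_id, gene5_name = g5$gene_name,
      gene3_id = g3$gene_id, gene3_name = g3$gene_name,
      chrom5 = s5$chrom, rna_bp5 = s5$rna, strand5 = s5$strand,
      chrom3 = s3$chrom, rna_bp3 = s3$rna, strand3 = s3$strand,
      sv_pos5 = NA_integer_, ori5 = NA_character_,
      sv_pos3 = NA_integer_, ori3 = NA_character_,
      sv_type = NA_character_, d5 = NA_integer_, d3 = NA_integer_,
      callers = "", ffpm = round(stats::runif(1, 0.11, 1.5), 2),
      tumor_var = NA_integer_, tumor_ref = NA_integer_,
      normal_var = NA_integer_, normal_ref = NA_integer_,
      expected_class = NA_character_, expected_high_confidence = FALSE,
      expected_level = NA_character_, long_offset = FALSE,
      stringsAsFactors = FALSE
    )
    truth[[length(truth) + 1L]] <- ev
    add_rna_rows(assign_fp[i], ev, both = FALSE,
                 which_caller = if (i %% 2 == 0) "sf" else "fc")
  }

  # population SVs: intergenic deletions present in every caller's VCF
  pop_rows <- list()
  for (i in seq_len(cfg$n_population_sv)) {
    contig <- sv_contigs[(i - 1) %% length(sv_contigs) + 1]
    on_contig <- genome$genes[genome$genes$contig == contig, ]
    anchor <- max(on_contig$end)
    lo <- anchor + 15000L + (i - 1L) * 6000L
    hi <- lo + sample(1500:3000, 1)
    eid <- eid + 1L
    ev <- data.frame(
      event_id = sprintf("E%03d", eid), patient_id = assign_pop[i],
      kind = "population_sv",
      gene5_id = NA_character_, gene5_name = NA_character_,
      gene3_id = NA_character_, gene3_name = NA_character_,
      chrom5 = contig, rna_bp5 = NA_integer_, strand5 = NA_character_,
      chrom3 = contig, rna_bp3 = NA_integer_, strand3 = NA_character_,
      sv_pos5 = lo, ori5 = "left", sv_pos3 = hi, ori3 = "right",
      sv_type = "DEL", d5 = NA_integer_, d3 = NA_integer_,
      callers = paste(callers, collapse = ","),
      ffpm = NA_real_,
      tumor_var = sample(18:40, 1), tumor_ref = sample(18:40, 1),
      normal_var = sample(18:40, 1), normal_ref = sample(18:40, 1),
      expected_class = NA_character_, expected_high_confidence = FALSE,
      expected_level = NA_character_, long_offset = FALSE,
      stringsAsFactors = FALSE
    )
    truth[[length(truth) + 1L]] <- ev
    for (cl in callers) {
      sv_records[[assign_pop[i]]][[cl]][[
        length(sv_records[[assign_pop[i]]][[cl]]) + 1L]] <-
        list(ev = ev, caller = cl)
    }
    pop_rows[[i]] <- data.frame(chrom = contig, start = lo, end = hi,
                                sv_type = "DEL", stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, truth)

  # --- write per-patient RNA tables and VCFs ---------------------------
  paths <- list(patients = list())
  for (p in patients) {
    pdir <- file.path(out_dir, "patients", p)
    sf_path <- file.path(pdir, "star_fusion.tsv")
    fc_path <- file.path(pdir, "fusioncatcher.tsv")
    write_star_fusion_table(do.call(rbind, rna_rows[[p]]$sf), sf_path)
    write_fusioncatcher_table(do.call(rbind, rna_rows[[p]]$fc), fc_path)
    vcfs <- list()
    for (cl in callers) {
      vp <- file.path(pdir, paste0(cl, ".vcf"))
      write_caller_vcf(sv_records[[p]][[cl]], cl, cfg, genome$contigs, vp)
      vcfs[[cl]] <- vp
    }
    paths$patients[[p]] <- list(star_fusion = sf_path, fusioncatcher = fc_path,
                                sv_vcfs = vcfs)
  }

  # --- annotation resources --------------------------------------------
  res_dir <- file.path(out_dir, "resources")
  healthy <- rbind(
    do.call(rbind, lapply(rt_events[seq_len(min(4, length(rt_events)))],
      function(e) data.frame(gene5 = e$gene5_name, gene3 = e$gene3_name))),
    data.frame(gene5 = c("DECOY1", "DECOY2"), gene3 = c("DECOY3", "DECOY4"))
  )
  cancer <- rbind(
    do.call(rbind, lapply(true_events[1:2], function(e) {
      data.frame(gene5 = e$gene5_name, gene3 = e$gene3_name)
    })),
    data.frame(gene5 = "DECOY5", gene3 = "DECOY6")
  )
  # population rows: the planted intergenic SVs, one exact match for the
  # first germline fusion span, and one 49%-reciprocal-overlap decoy for
  # the second (just below the 50% criterion)
  g1 <- germline_events[[1]]; g2 <- germline_events[[2]]
  sp1 <- sort(c(g1$sv_pos5, g1$sv_pos3)); sp2 <- sort(c(g2$sv_pos5, g2$sv_pos3))
  L2 <- sp2[2] - sp2[1] + 1L
  shift2 <- ceiling(0.51 * L2)
  pop_extra <- rbind(
    data.frame(chrom = g1$chrom5, start = sp1[1], end = sp1[2],
               sv_type = g1$sv_type, stringsAsFactors = FALSE),
    data.frame(chrom = g2$chrom5, start = sp2[1] + shift2,
               end = sp2[2] + shift2, sv_type = g2$sv_type,
               stringsAsFactors = FALSE)
  )
  pop_tab <- rbind(do.call(rbind, pop_rows), pop_extra)
  utils::write.table(pop_tab, file.path(res_dir, "population_svs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(healthy, file.path(res_dir, "healthy_chimera.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cancer, file.path(res_dir, "cancer_chimera.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # repeats: SINE elements straddling the breakends of a germline CTX
  # when one exists (otherwise of the last germline event), plus decoys
  # exercising the class and completeness pre-filters
  ctx_idx <- which(vapply(germline_events, function(e) e$sv_type == "CTX",
                          TRUE))
  rep_ev <- germline_events[[if (length(ctx_idx)) ctx_idx[1] else
    length(germline_events)]]
  reps <- rbind(
    data.frame(chrom = rep_ev$chrom5, start = rep_ev$sv_pos5 - 60L,
               end = rep_ev$sv_pos5 + 60L, repeat_class = "SINE",
               repeat_family = "AluY", bp_missing = 4L),
    data.frame(chrom = rep_ev$chrom3, start = rep_ev$sv_pos3 - 60L,
               end = rep_ev$sv_pos3 + 60L, repeat_class = "SINE",
               repeat_family = "AluSx", bp_missing = 9L),
    data.frame(chrom = genome$contigs[1], start = 1000L, end = 6500L,
               repeat_class = "LINE", repeat_family = "L1", bp_missing = 30L),
    data.frame(chrom = genome$contigs[1], start = 9000L, end = 9600L,
               repeat_class = "LTR", repeat_family = "ERVL", bp_missing = 0L),
    # truncated element: removed by the completeness pre-filter
    data.frame(chrom = rep_ev$chrom5, start = rep_ev$sv_pos5 - 30L,
               end = rep_ev$sv_pos5 + 30L, repeat_class = "LINE",
               repeat_family = "L2", bp_missing = 4000L),
    # wrong class: removed by the class pre-filter
    data.frame(chrom = rep_ev$chrom5, start = rep_ev$sv_pos5 - 10L,
               end = rep_ev$sv_pos5 + 10L, repeat_class = "Simple_repeat",
               repeat_family = "(TA)n", bp_missing = 0L)
  )
  utils::write.table(reps, file.path(res_dir, "repeats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  segdup_ev <- germline_events[[length(germline_events)]]
  segdups <- data.frame(chrom = segdup_ev$chrom5,
                        start = segdup_ev$sv_pos5 - 500L,
                        end = segdup_ev$sv_pos5 + 500L)
  utils::write.table(segdups, file.path(res_dir, "segdups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gene_lists <- rbind(
    data.frame(gene = true_events[[1]]$gene3_name, category = "oncogene"),
    data.frame(gene = true_events[[2]]$gene5_name, category = "tsg"),
    data.frame(gene = true_events[[3]]$gene3_name, category = "kinase"),
    data.frame(gene = true_events[[1]]$gene5_name,
               category = "clinically_relevant"),
    data.frame(gene = low_af_events[[1]]$gene3_name, category = "oncogene"),
    data.frame(gene = "DECOY7", category = "oncogene")
  )
  utils::write.table(gene_lists, file.path(res_dir, "gene_lists.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- expression / copy number / FGA ----------------------------------
  genes_all <- genome$genes$gene_id
  baseline <- round(stats::runif(length(genes_all), 5, 50), 2)
  fpkm <- matrix(0, nrow = length(genes_all), ncol = cfg$n_patients,
                 dimnames = list(genes_all, patients))
  for (j in seq_len(cfg$n_patients)) {
    fpkm[, j] <- round(baseline * 2^stats::rnorm(length(genes_all), 0, 0.1), 3)
  }
  cn <- matrix(round(stats::rnorm(length(genes_all) * cfg$n_patients, 0, 0.05), 3),
               nrow = length(genes_all), dimnames = list(genes_all, patients))
  # amplified low-AF events: high copy number and 16-fold overexpression
  # of the 3' partner
  for (e in low_af_events) {
    cn[e$gene5_id, e$patient_id] <- round(stats::runif(1, 2.2, 3.2), 3)
    cn[e$gene3_id, e$patient_id] <- round(stats::runif(1, 2.2, 3.2), 3)
    fpkm[e$gene3_id, e$patient_id] <- round(16 * fpkm[e$gene3_id, e$patient_id], 3)
  }
  # a couple of plain copy-number gains on true-fusion 3' partners
  for (e in true_events[seq(min(5L, length(true_events)),
                            min(6L, length(true_events)))]) {
    cn[e$gene3_id, e$patient_id] <- round(stats::runif(1, 0.7, 1.2), 3)
  }
  # one silenced 5' partner (disrupted allele): near-zero expression
  sil <- germline_events[[1]]
  fpkm[sil$gene5_id, sil$patient_id] <- 0.01

  supergroup <- data.frame(
    sample = patients,
    supergroup = rep(c("SGA", "SGB"), each = cfg$n_patients / 2)[seq_len(cfg$n_patients)]
  )

  hcF <- truth[truth$expected_high_confidence &
                 truth$kind %in% c("true_fusion", "germline_sv_fusion",
                                   "low_af_amplicon_fusion"), ]
  n_hcf <- vapply(patients, function(p) sum(hcF$patient_id == p), 1L)
  fga <- ifelse(n_hcf >= 5, round(stats::runif(cfg$n_patients, 0.55, 0.75), 4),
                round(stats::runif(cfg$n_patients, 0.005, 0.12), 4))

  exp_dir <- file.path(out_dir, "expression")
  write_matrix_tsv(fpkm, "gene_id", file.path(exp_dir, "fpkm.tsv"))
  write_matrix_tsv(cn, "gene_id", file.path(exp_dir, "cn_l2fc.tsv"))
  utils::write.table(supergroup, file.path(exp_dir, "supergroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = patients, fga = fga),
                     file.path(exp_dir, "fga.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_lines <- c(
    sprintf("synthetic cohort: %d patients, %d events, seed %d",
            cfg$n_patients, nrow(truth), seed),
    sprintf("  %s: %d", names(table(truth$kind)), as.integer(table(truth$kind))),
    sprintf("expected high-confidence fusions: %d", sum(truth$expected_high_confidence)),
    sprintf("high-burden patients (>= 5 expected hcF): %s",
            paste(patients[n_hcf >= 5], collapse = ", "))
  )
  writeLines(summary_lines, file.path(out_dir, "manifest_summary.txt"))

  attr(truth, "paths") <- c(paths, list(
    resources = list(
      healthy_chimera = file.path(res_dir, "healthy_chimera.tsv"),
      cancer_chimera = file.path(res_dir, "cancer_chimera.tsv"),
      population_svs = file.path(res_dir, "population_svs.tsv"),
      repeats = file.path(res_dir, "repeats.tsv"),
      segdups = file.path(res_dir, "segdups.tsv"),
      gene_lists = file.path(res_dir, "gene_lists.tsv")
    ),
    expression = list(
      fpkm = file.path(exp_dir, "fpkm.tsv"),
      cn_l2fc = file.path(exp_dir, "cn_l2fc.tsv"),
      supergroups = file.path(exp_dir, "supergroups.tsv"),
      fga = file.path(exp_dir, "fga.tsv")
    ),
    truth = file.path(out_dir, "truth.tsv")
  ))
  attr(truth, "expected") <- data.frame(patient_id = patients,
                                        expected_n_hcf = unname(n_hcf),
                                        fga = unname(fga))
  attr(truth, "special") <- list(
    repeat_hit_event = rep_ev$event_id,
    segdup_hit_event = segdup_ev$event_id,
    population_exact_event = g1$event_id,
    population_boundary_event = g2$event_id,
    silenced = list(gene = sil$gene5_id, sample = sil$patient_id),
    overexpressed = data.frame(
      gene = vapply(low_af_events, function(e) e$gene3_id, ""),
      sample = vapply(low_af_events, function(e) e$patient_id, ""),
      stringsAsFactors = FALSE
    )
  )
  truth
}

# --- dialect writers ------------------------------------------------------

write_star_fusion_table <- function(rows, path) {
  header <- paste("#FusionName", "JunctionReadCount", "SpanningFragCount",
                  "LeftGene", "LeftBreakpoint", "RightGene",
                  "RightBreakpoint", "FFPM", "annots", sep = "\t")
  lines <- header
  if (!is.null(rows) && nrow(rows)) {
    lines <- c(lines, vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      paste(r$fusion, r$junction, r$spanning, r$left_gene, r$left_bp,
            r$right_gene, r$right_bp, sprintf("%.2f", r$ffpm), r$annots,
            sep = "\t")
    }, ""))
  }
  writeLines(lines, path)
}

write_fusioncatcher_table <- function(rows, path) {
  header <- paste("Gene_1_symbol(5end_fusion_partner)",
                  "Gene_2_symbol(3end_fusion_partner)",
                  "Fusion_description",
                  "Spanning_pairs", "Spanning_unique_reads",
                  "Fusion_point_for_gene_1(5end_fusion_partner)",
                  "Fusion_point_for_gene_2(3end_fusion_partner)",
                  "Gene_1_id(5end_fusion_partner)",
                  "Gene_2_id(3end_fusion_partner)", sep = "\t")
  lines <- header
  if (!is.null(rows) && nrow(rows)) {
    lines <- c(lines, vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      paste(r$g5, r$g3, r$desc, r$spanning, r$junction, r$bp5, r$bp3,
            r$g5id, r$g3id, sep = "\t")
    }, ""))
  }
  writeLines(lines, path)
}

# FORMAT strings per dialect, splitting variant/reference evidence into
# the caller's paired-end and split-read fields
format_sample <- function(caller, var, ref) {
  v1 <- var %/% 2L; v2 <- var - v1
  r1 <- ref %/% 2L; r2 <- ref - r1
  switch(caller,
    manta = sprintf("%d,%d:%d,%d", r1, v1, r2, v2),       # PR:SR = ref,var
    delly = sprintf("%d:%d:%d:%d", r1, v1, r2, v2),        # DR:DV:RR:RV
    gridss = sprintf("%d:%d:%d", var, r1, r2),             # VF:REF:REFPAIR
    generic = sprintf("%d:%d", var, ref)
  )
}

caller_format_keys <- function(caller) {
  switch(caller,
    manta = "PR:SR", delly = "DR:DV:RR:RV", gridss = "VF:REF:REFPAIR",
    generic = "VR:RR")
}

write_caller_vcf <- function(records, caller, cfg, contigs, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=%s-synthetic", caller),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=CT,Number=1,Type=String,Description=\"Breakend orientation\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"CI around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"CI around END\">",
    switch(caller,
      manta = c(
        "##FORMAT=<ID=PR,Number=.,Type=Integer,Description=\"Paired reads ref,alt\">",
        "##FORMAT=<ID=SR,Number=.,Type=Integer,Description=\"Split reads ref,alt\">"),
      delly = c(
        "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Reference pairs\">",
        "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Variant pairs\">",
        "##FORMAT=<ID=RR,Number=1,Type=Integer,Description=\"Reference junction reads\">",
        "##FORMAT=<ID=RV,Number=1,Type=Integer,Description=\"Variant junction reads\">"),
      gridss = c(
        "##FORMAT=<ID=VF,Number=1,Type=Integer,Description=\"Variant fragments\">",
        "##FORMAT=<ID=REF,Number=1,Type=Integer,Description=\"Reference reads\">",
        "##FORMAT=<ID=REFPAIR,Number=1,Type=Integer,Description=\"Reference pairs\">")
    ),
    paste0("##contig=<ID=", contigs, ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR"
  )
  fmt <- caller_format_keys(caller)
  lines <- character(0)
  ridx <- 0L
  for (rec in records) {
    ev <- rec$ev
    ridx <- ridx + 1L
    hw <- cfg$footprint_halfwidth[[caller]]
    # occasional broad assembly footprint (delly only, designated draws)
    if (caller == "delly" && stats::runif(1) < 0.08) {
      hw <- cfg$broad_footprint_halfwidths[
        sample.int(length(cfg$broad_footprint_halfwidths), 1)]
    }
    jit <- function(pos) {
      if (cfg$jitter_sd > 0) pos + as.integer(round(stats::rnorm(1, 0, cfg$jitter_sd)))
      else pos
    }
    p5 <- jit(ev$sv_pos5); p3 <- jit(ev$sv_pos3)
    nrm <- format_sample(caller, ev$normal_var, ev$normal_ref)
    tmr <- format_sample(caller, ev$tumor_var, ev$tumor_ref)
    id_base <- sprintf("%s_%s_%03d", toupper(caller), ev$event_id, ridx)

    intra <- ev$chrom5 == ev$chrom3
    symbolic <- intra && (
      (caller == "manta" && ev$sv_type %in% c("DEL", "DUP")) ||
      (caller == "delly" && ev$sv_type %in% c("DEL", "DUP", "INV"))
    )
    if (symbolic) {
      lo <- min(p5, p3); hi <- max(p5, p3)
      ori_lo <- if (p5 <= p3) ev$ori5 else ev$ori3
      ori_hi <- if (p5 <= p3) ev$ori3 else ev$ori5
      ct <- if (ori_lo == "left" && ori_hi == "right") "3to5"
        else if (ori_lo == "right" && ori_hi == "left") "5to3"
        else if (ori_lo == "left") "3to3" else "5to5"
      info <- sprintf("SVTYPE=%s;END=%d;CT=%s;CIPOS=-%d,%d;CIEND=-%d,%d",
                      ev$sv_type, hi, ct, hw, hw, hw, hw)
      lines <- c(lines, paste(ev$chrom5, lo, id_base, "N",
                              paste0("<", ev$sv_type, ">"), "60", "PASS",
                              info, fmt, nrm, tmr, sep = "\t"))
    } else {
      ids <- paste0(id_base, c("_bnd1", "_bnd2"))
      alt1 <- make_bnd_alt(ev$ori5, ev$chrom3, p3, ev$ori3)
      alt2 <- make_bnd_alt(ev$ori3, ev$chrom5, p5, ev$ori5)
      ci <- sprintf("CIPOS=-%d,%d", hw, hw)
      lines <- c(lines,
        paste(ev$chrom5, p5, ids[1], "N", alt1, "60", "PASS",
              sprintf("SVTYPE=BND;MATEID=%s;%s", ids[2], ci),
              fmt, nrm, tmr, sep = "\t"),
        paste(ev$chrom3, p3, ids[2], "N", alt2, "60", "PASS",
              sprintf("SVTYPE=BND;MATEID=%s;%s", ids[1], ci),
              fmt, nrm, tmr, sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), path)
}

write_matrix_tsv <- function(m, id_col, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
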