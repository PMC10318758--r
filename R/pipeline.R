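#' Resolve the fusions of one patient
#'
#' Runs the full integration for one patient: read both RNA callers'
#' predictions, merge them on oriented gene pairs, read and normalize the
#' SV calls of all WGS callers, match SV breakends to each prediction's
#' matching-interval hierarchies, build per-fusion multi-caller
#' consensuses, classify somatic status, and (when resources are given)
#' annotate. When one RNA caller's input is missing the run proceeds with
#' a loud warning -- no prediction can then be `predicted_by_both_rna`,
#' so no fusion can reach high confidence.
#'
#' @param star_fusion,fusioncatcher Paths to the two RNA callers' TSVs
#'   (either may be NULL/missing).
#' @param sv_vcfs Named list of VCF paths; names are dialects from
#'   [sv_dialects()] (e.g. `list(manta = ..., delly = ..., gridss = ...)`).
#' @param model A `GeneModel` from [parse_gtf()].
#' @param patient_id Patient identifier.
#' @param resources Optional `AnnotationResources`.
#' @param cfg A [fusion_config()].
#' @param out_file Optional path: write the report TSV with a provenance
#'   header via [write_report()].
#' @return List of class `fusion_run`:
#'   \describe{
#'     \item{report}{data.frame of resolved fusions (one row per fusion
#'       with SV support), incl. somatic class, high-confidence flag,
#'       match levels, FFPM and low-expression flag.}
#'     \item{merged}{the merged RNA predictions.}
#'     \item{funnel}{named stage counts: predictions in both callers,
#'       merged gene pairs, SV-matched fusions, high-confidence fusions,
#'       and the per-class tallies.}
#'     \item{skipped}{gene pairs skipped for lack of annotation.}
#'   }
#' @export
run_resolve <- function(star_fusion = NULL, fusioncatcher = NULL,
                        sv_vcfs = list(), model, patient_id = "patient",
                        resources = NULL, cfg = fusion_config(),
                        out_file = NULL) {
  preds_a <- if (!is.null(star_fusion) && file.exists(star_fusion)) {
    read_star_fusion(star_fusion, patient_id)
  } else {
    warning("no STAR-Fusion-style input for ", patient_id,
            ": predictions cannot be supported by both RNA callers")
    empty_predictions()
  }
  preds_b <- if (!is.null(fusioncatcher) && file.exists(fusioncatcher)) {
    read_fusioncatcher(fusioncatcher, patient_id, cfg$total_fragments)
  } else {
    warning("no FusionCatcher-style input for ", patient_id,
            ": predictions cannot be supported by both RNA callers")
    empty_predictions()
  }
  merged <- merge_predictions(preds_a, preds_b, cfg$ffpm_threshold)

  svs <- do.call(rbind, lapply(names(sv_vcfs), function(cl) {
    read_sv_vcf(sv_vcfs[[cl]], dialect = cl)
  }))
  if (is.null(svs)) svs <- empty_svs()

  resolved <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(merged))) {
    pred <- merged[i, , drop = FALSE]
    supports <- match_fusion_to_svs(pred, model, svs, cfg)
    if (!is.null(attr(supports, "reason"))) {
      skipped <- c(skipped, paste0(pred$gene5_id, "--", pred$gene3_id, ":",
                                   attr(supports, "reason")))
      next
    }
    rf <- build_consensus(pred, supports, svs, cfg)
    if (!is.null(rf)) resolved[[length(resolved) + 1L]] <- rf
  }
  report <- if (length(resolved)) do.call(rbind, resolved) else NULL
  if (is.null(report)) {
    report <- empty_report()
  } else {
    report <- cbind(patient_id = patient_id, report)
    rownames(report) <- NULL
  }
  healthy_flags <- if (nrow(report)) {
    key <- paste(report$gene5_id, report$gene3_id)
    mkey <- paste(merged$gene5_id, merged$gene3_id)
    merged$healthy_flag[match(key, mkey)]
  } else {
    logical(0)
  }
  if (!is.null(resources) && nrow(report)) {
    report <- annotate_fusions(report, resources, healthy_flags, cfg)
  }

  funnel <- c(
    predictions_total = nrow(preds_a) + nrow(preds_b),
    merged_gene_pairs = nrow(merged),
    sv_matched = nrow(report),
    high_confidence = sum(report$high_confidence),
    tumor_specific = sum(report$high_confidence &
                           report$somatic_class == "tumor_specific"),
    germline = sum(report$high_confidence &
                     report$somatic_class == "germline"),
    low_af = sum(report$high_confidence & report$somatic_class == "low_af")
  )
  run <- structure(
    list(report = report, merged = merged, funnel = funnel,
         skipped = skipped, patient_id = patient_id),
    class = "fusion_run"
  )
  if (!is.null(out_file)) write_report(report, out_file, cfg)
  run
}

empty_report <- function() {
  data.frame(
    patient_id = character(0),
    gene5_id = character(0), gene3_id = character(0),
    gene5_name = character(0), gene3_name = character(0),
    chrom1 = character(0), pos1 = integer(0),
    chrom2 = character(0), pos2 = integer(0),
    sv_type = character(0), sv_length = numeric(0),
    n_sv_callers = integer(0), sv_callers = character(0),
    predicted_by_both_rna = logical(0), high_confidence = logical(0),
    composite = logical(0), filtered_only = logical(0),
    tumor_af = numeric(0), normal_af = numeric(0),
    somatic_class = character(0),
    level5 = character(0), level3 = character(0),
    dist5 = numeric(0), dist3 = numeric(0),
    max_ffpm = numeric(0), low_expression = logical(0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.fusion_run <- function(x, ...) {
  cat("fusion_run for", x$patient_id, "\n")
  for (k in names(x$funnel)) cat(sprintf("  %-20s %d\n", k, x$funnel[[k]]))
  invisible(x)
}

#' Write a fusion report TSV with a provenance header
#'
#' Every configuration threshold is echoed as a `#key=value` line before
#' the column header, so any report can be traced back to the exact
#' settings that produced it.
#'
#' @param report data.frame of resolved fusions.
#' @param path Output path.
#' @param cfg The [fusion_config()] used to produce the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, cfg = fusion_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(cfg), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a fusion report written by [write_report()]
#'
#' @param path Report TSV (provenance header lines start with `#`).
#' @return data.frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Combine per-patient runs into a cohort report
#'
#' Maps high-confidence fusions to distinct fusions with recurrence
#' counts across patients and, when an expression context with FGA
#' values is available, tests the association between high fusion burden
#' and the fraction of genome altered.
#'
#' @param runs List of `fusion_run` objects (or data.frames of resolved
#'   fusions with a `patient_id` column).
#' @param ctx Optional `ExpressionContext` carrying per-sample `fga`.
#' @param cfg A [fusion_config()].
#' @return List of class `fusion_cohort`: `combined` (all resolved
#'   fusions), `distinct` (distinct high-confidence fusions with
#'   recurrence), `burden` (per-patient high-confidence counts, with FGA
#'   when available), `burden_test` ([burden_vs_fga()] output or NULL).
#' @export
run_cohort <- function(runs, ctx = NULL, cfg = fusion_config()) {
  tables <- lapply(runs, function(r) if (inherits(r, "fusion_run")) r$report else r)
  tables <- tables[vapply(tables, nrow, 1L) > 0]
  combined <- if (length(tables)) {
    shared <- Reduce(intersect, lapply(tables, names))
    do.call(rbind, lapply(tables, function(t) t[, shared, drop = FALSE]))
  } else {
    empty_report()
  }
  rownames(combined) <- NULL
  hc <- combined[combined$high_confidence, , drop = FALSE]
  distinct <- map_to_distinct(hc)

  patient_ids <- vapply(runs, function(r) {
    if (inherits(r, "fusion_run")) r$patient_id else unique(r$patient_id)[1]
  }, "")
  burden <- data.frame(
    patient_id = patient_ids,
    n_hcf = vapply(patient_ids, function(p) {
      sum(hc$patient_id == p)
    }, 1L),
    stringsAsFactors = FALSE
  )
  burden_test <- NULL
  if (!is.null(ctx) && !is.null(ctx$fga)) {
    burden$fga <- unname(ctx$fga[burden$patient_id])
    ok <- !is.na(burden$fga)
    if (sum(ok) >= 2) burden_test <- burden_vs_fga(burden[ok, ], cfg)
  }
  structure(
    list(combined = combined, distinct = distinct, burden = burden,
         burden_test = burden_test),
    class = "fusion_cohort"
  )
}

#' @export
print.fusion_cohort <- function(x, ...) {
  cat("fusion_cohort:", nrow(x$combined), "resolved fusions,",
      nrow(x$distinct), "distinct high-confidence fusions\n")
  if (!is.null(x$burden_test)) {
    bt <- x$burden_test
    cat(sprintf("  burden vs FGA: median %.3f vs %.3f, %s p = %.2g\n",
                bt$median_high, bt$median_low, bt$method, bt$p_value))
  }
  invisible(x)
}

#' Simulate a synthetic cohort on disk
#'
#' Thin wrapper over [generate_toy_genome()] and [plant_cohort()].
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (genome and cohort derive their own
#'   sub-seeds from it).
#' @param genome_cfg A [toy_genome_config()].
#' @param cohort_cfg A [cohort_config()].
#' @return The truth manifest (see [plant_cohort()]), with the genome
#'   attached as attribute `genome`.
#' @export
run_simulate <- function(out_dir, seed = 1L,
                         genome_cfg = toy_genome_config(),
                         cohort_cfg = cohort_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_toy_genome(file.path(out_dir, "genome.gtf"),
                                genome_cfg, seed = seed)
  truth <- plant_cohort(genome, out_dir, cohort_cfg, seed = seed + 1L)
  attr(truth, "genome") <- genome
  truth
}

#' Resolve every patient of a simulated cohort directory
#'
#' Convenience driver for cohorts laid out by [run_simulate()]: parses
#' the genome annotation, loads the annotation resources and expression
#' context, resolves each patient and assembles the cohort report.
#'
#' @param cohort_dir Directory produced by [run_simulate()].
#' @param cfg A [fusion_config()].
#' @param annotate Load and apply the annotation resources. Default TRUE.
#' @return List: `runs` (named per-patient `fusion_run`s), `cohort`
#'   ([run_cohort()] output), `model`, `ctx`.
#' @export
resolve_cohort_dir <- function(cohort_dir, cfg = fusion_config(),
                               annotate = TRUE) {
  model <- parse_gtf(file.path(cohort_dir, "genome.gtf"))
  res_dir <- file.path(cohort_dir, "resources")
  resources <- if (annotate) {
    load_annotation_resources(
      healthy_chimera = file.path(res_dir, "healthy_chimera.tsv"),
      cancer_chimera = file.path(res_dir, "cancer_chimera.tsv"),
      population_svs = file.path(res_dir, "population_svs.tsv"),
      repeats = file.path(res_dir, "repeats.tsv"),
      segdups = file.path(res_dir, "segdups.tsv"),
      gene_lists = file.path(res_dir, "gene_lists.tsv"),
      cfg = cfg
    )
  } else {
    NULL
  }
  exp_dir <- file.path(cohort_dir, "expression")
  ctx <- read_expression_context(
    fpkm_path = file.path(exp_dir, "fpkm.tsv"),
    supergroup_path = file.path(exp_dir, "supergroups.tsv"),
    cn_l2fc_path = file.path(exp_dir, "cn_l2fc.tsv"),
    fga_path = file.path(exp_dir, "fga.tsv")
  )
  patient_dirs <- list.dirs(file.path(cohort_dir, "patients"),
                            recursive = FALSE)
  runs <- lapply(patient_dirs, function(pd) {
    run_resolve(
      star_fusion = file.path(pd, "star_fusion.tsv"),
      fusioncatcher = file.path(pd, "fusioncatcher.tsv"),
      sv_vcfs = list(manta = file.path(pd, "manta.vcf"),
                     delly = file.path(pd, "delly.vcf"),
                     gridss = file.path(pd, "gridss.vcf")),
      model = model, patient_id = basename(pd), resources = resources,
      cfg = cfg
    )
  })
  names(runs) <- basename(patient_dirs)
  list(runs = runs, cohort = run_cohort(runs, ctx, cfg), model = model,
       ctx = ctx)
}
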