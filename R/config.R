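#' Pipeline configuration
#'
#' Collects every tunable threshold used across the pipeline in one named
#' list. All thresholds are echoed verbatim into the provenance header of
#' every report written by [write_report()], so a report always records the
#' configuration that produced it.
#'
#' @param flank_bp Flank (bp) added around the transcript span for the
#'   `gene_flank` matching level. Default 10000.
#' @param exon_boundary_tolerance_bp Tolerance (bp) when deciding whether an
#'   RNA breakpoint coincides with an exon boundary; RNA aligners
#'   occasionally shift splice junctions by a few bases. Default 3.
#' @param noncanonical_window_bp Half-width (bp) of the fallback matching
#'   window used when an RNA breakpoint does not coincide with any exon
#'   boundary. Default 1000.
#' @param ffpm_threshold Fusion fragments per million below which a
#'   prediction is flagged `low_expression`. Never used as a filter: lowly
#'   expressed predictions are carried through matching and rescued when SV
#'   support exists. Default 0.1.
#' @param min_callers Minimum number of distinct SV callers in a consensus
#'   for a fusion to be high confidence. Default 2.
#' @param min_recip Minimum reciprocal overlap between intrachromosomal SV
#'   calls to cluster them into one consensus. Default 0.5.
#' @param ctx_max_dist Maximum breakend distance (bp) to cluster
#'   interchromosomal translocation calls, which have no span for reciprocal
#'   overlap. Default 1000.
#' @param germline_normal_af_min Normal-sample allele fraction at or above
#'   which a fusion SV is classified germline. Default 0.10.
#' @param tumor_af_min Tumor-sample allele fraction at or above which a
#'   non-germline fusion SV is classified tumor-specific (below: low allele
#'   fraction). Default 0.10.
#' @param cn_gain_l2fc Copy-number log2 fold change above which a gene is
#'   called a gain. Default 0.58.
#' @param cn_amplified_l2fc Copy-number log2 fold change above which a gene
#'   is called amplified. Default 1.58.
#' @param cn_loss_l2fc Copy-number log2 fold change below which a gene is
#'   called a loss (mirror of the gain threshold). Default -0.58.
#' @param zfpkm_cut Absolute expression z-score beyond which a gene is
#'   flagged over-/under-expressed relative to its cancer-type supergroup.
#'   Default 1.96.
#' @param zfpkm_log Compute expression z-scores on log2(FPKM + 1) rather
#'   than raw FPKM. Default TRUE.
#' @param min_group_size Minimum number of samples in a supergroup for a
#'   z-score to be computed. Default 3.
#' @param high_burden_min Number of high-confidence fusions at or above
#'   which a patient counts as high fusion burden. Default 5.
#' @param interval_mode `"hierarchy"` (intron-exact / gene-body /
#'   gene-flank levels derived from gene structure) or `"fixed_window"` (a
#'   fixed-size window centered on the RNA breakpoint, provided for
#'   comparison experiments). Default `"hierarchy"`.
#' @param fixed_window_bp Total size (bp) of the fixed matching window in
#'   `"fixed_window"` mode. Default 10000.
#' @param symmetric_chimera Match chimera gene pairs ignoring 5'/3'
#'   orientation. Default FALSE.
#' @param popsv_type_aware Require compatible SV type when matching
#'   population SVs (a deletion overlapping a common duplication is not the
#'   same variant). Default TRUE.
#' @param repeat_completeness_mode `"max_remaining"` keeps repeat elements
#'   with fewer than `repeat_completeness_bp` bases missing (near-complete
#'   elements); `"min_remaining"` keeps elements with at least that many
#'   bases present. Default `"max_remaining"`.
#' @param repeat_completeness_bp Threshold (bp) for the repeat completeness
#'   pre-filter. Default 50.
#' @param total_fragments Total RNA-seq fragments per library, used to
#'   convert read counts to FFPM when a caller does not report FFPM itself.
#'   Default 1e8.
#'
#' @return A named list of class `"fusion_config"`.
#' @export
fusion_config <- function(flank_bp = 10000L,
                          exon_boundary_tolerance_bp = 3L,
                          noncanonical_window_bp = 1000L,
                          ffpm_threshold = 0.1,
                          min_callers = 2L,
                          min_recip = 0.5,
                          ctx_max_dist = 1000L,
                          germline_normal_af_min = 0.10,
                          tumor_af_min = 0.10,
                          cn_gain_l2fc = 0.58,
                          cn_amplified_l2fc = 1.58,
                          cn_loss_l2fc = -0.58,
                          zfpkm_cut = 1.96,
                          zfpkm_log = TRUE,
                          min_group_size = 3L,
                          high_burden_min = 5L,
                          interval_mode = c("hierarchy", "fixed_window"),
                          fixed_window_bp = 10000L,
                          symmetric_chimera = FALSE,
                          popsv_type_aware = TRUE,
                          repeat_completeness_mode = c("max_remaining", "min_remaining"),
                          repeat_completeness_bp = 50L,
                          total_fragments = 1e8) {
  cfg <- list(
    flank_bp = as.integer(flank_bp),
    exon_boundary_tolerance_bp = as.integer(exon_boundary_tolerance_bp),
    noncanonical_window_bp = as.integer(noncanonical_window_bp),
    ffpm_threshold = ffpm_threshold,
    min_callers = as.integer(min_callers),
    min_recip = min_recip,
    ctx_max_dist = as.integer(ctx_max_dist),
    germline_normal_af_min = germline_normal_af_min,
    tumor_af_min = tumor_af_min,
    cn_gain_l2fc = cn_gain_l2fc,
    cn_amplified_l2fc = cn_amplified_l2fc,
    cn_loss_l2fc = cn_loss_l2fc,
    zfpkm_cut = zfpkm_cut,
    zfpkm_log = isTRUE(zfpkm_log),
    min_group_size = as.integer(min_group_size),
    high_burden_min = as.integer(high_burden_min),
    interval_mode = match.arg(interval_mode),
    fixed_window_bp = as.integer(fixed_window_bp),
    symmetric_chimera = isTRUE(symmetric_chimera),
    popsv_type_aware = isTRUE(popsv_type_aware),
    repeat_completeness_mode = match.arg(repeat_completeness_mode),
    repeat_completeness_bp = as.integer(repeat_completeness_bp),
    total_fragments = total_fragments
  )
  class(cfg) <- "fusion_config"
  cfg
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("fusion_config with", length(x), "settings:\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Provenance header lines ('#key=value') for report files.
config_header <- function(cfg) {
  vapply(names(cfg), function(k) sprintf("#%s=%s", k, format(cfg[[k]])), "")
}
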