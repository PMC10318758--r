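#' Assemble an expression/copy-number context
#'
#' @param fpkm Numeric matrix of FPKM values, genes in rows, samples in
#'   columns (all values >= 0).
#' @param supergroup Named character vector mapping sample -> cancer-type
#'   supergroup label.
#' @param cn_l2fc Numeric matrix of copy-number log2 fold changes relative
#'   to each tumor's read-depth baseline, genes x samples (may be NULL).
#' @param fga Named numeric vector mapping sample -> fraction of genome
#'   altered, values in `[0, 1]` (may be NULL).
#' @return An `ExpressionContext` list.
#' @export
expression_context <- function(fpkm, supergroup, cn_l2fc = NULL, fga = NULL) {
  stopifnot(is.matrix(fpkm), all(fpkm >= 0, na.rm = TRUE))
  stopifnot(all(colnames(fpkm) %in% names(supergroup)))
  if (!is.null(fga)) stopifnot(all(fga >= 0 & fga <= 1, na.rm = TRUE))
  structure(
    list(fpkm = fpkm, supergroup = supergroup, cn_l2fc = cn_l2fc, fga = fga),
    class = "ExpressionContext"
  )
}

#' Read an expression/copy-number context from TSV files
#'
#' @param fpkm_path Genes-by-samples FPKM matrix TSV (first column gene).
#' @param supergroup_path TSV `sample, supergroup`.
#' @param cn_l2fc_path Optional genes-by-samples copy-number l2fc TSV.
#' @param fga_path Optional TSV `sample, fga`.
#' @return An `ExpressionContext`.
#' @export
read_expression_context <- function(fpkm_path, supergroup_path,
                                    cn_l2fc_path = NULL, fga_path = NULL) {
  read_matrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  sg <- utils::read.delim(supergroup_path, stringsAsFactors = FALSE)
  supergroup <- stats::setNames(sg[[2]], sg[[1]])
  fga <- NULL
  if (!is.null(fga_path)) {
    fg <- utils::read.delim(fga_path, stringsAsFactors = FALSE)
    fga <- stats::setNames(fg[[2]], fg[[1]])
  }
  expression_context(
    fpkm = read_matrix(fpkm_path),
    supergroup = supergroup,
    cn_l2fc = if (is.null(cn_l2fc_path)) NULL else read_matrix(cn_l2fc_path),
    fga = fga
  )
}

#' Expression z-score of a gene relative to its cancer-type supergroup
#'
#' The z-score is computed over the samples of the query sample's
#' supergroup, by default on log2(FPKM + 1) -- raw FPKM is heavily
#' right-skewed, which makes raw-scale z-scores misleading; the raw scale
#' remains selectable via `cfg$zfpkm_log`. Flags mark over-expression
#' (z > `cfg$zfpkm_cut`) and under-expression (z < -`cfg$zfpkm_cut`).
#' A nominal two-sided normal-tail p-value of the z-score is reported,
#' labeled as such in output metadata.
#'
#' @param gene Gene identifier (row of the FPKM matrix).
#' @param sample Sample identifier (column).
#' @param ctx An `ExpressionContext`.
#' @param cfg A [fusion_config()].
#' @return List: `z`, `over`, `under`, `p`, `group`, `n_group`, `reason`
#'   (`NA` or why z is missing: too-small group, zero spread, unknown
#'   gene/sample).
#' @export
compute_zfpkm <- function(gene, sample, ctx, cfg = fusion_config()) {
  out <- list(z = NA_real_, over = FALSE, under = FALSE, p = NA_real_,
              group = NA_character_, n_group = 0L, reason = NA_character_)
  if (!gene %in% rownames(ctx$fpkm) || !sample %in% colnames(ctx$fpkm)) {
    out$reason <- "unknown_gene_or_sample"
    return(out)
  }
  grp <- ctx$supergroup[[sample]]
  members <- names(ctx$supergroup)[ctx$supergroup == grp]
  members <- intersect(members, colnames(ctx$fpkm))
  out$group <- grp
  out$n_group <- length(members)
  if (length(members) < cfg$min_group_size) {
    out$reason <- "group_too_small"
    return(out)
  }
  vals <- ctx$fpkm[gene, members]
  if (cfg$zfpkm_log) vals <- log2(vals + 1)
  x <- vals[[sample]]
  s <- stats::sd(vals)
  if (is.na(s) || s == 0) {
    out$reason <- "zero_group_sd"
    return(out)
  }
  z <- (x - mean(vals)) / s
  out$z <- z
  out$over <- z > cfg$zfpkm_cut
  out$under <- z < -cfg$zfpkm_cut
  out$p <- 2 * stats::pnorm(-abs(z))
  out
}

#' Classify copy-number status from a log2 fold change
#'
#' Thresholds follow the convention for read-depth ratios relative to a
#' diploid baseline: above 1.58 amplified, above 0.58 gain, below -0.58
#' loss (the loss threshold mirrors the gain threshold), otherwise
#' neutral; missing values are `"unknown"`. The classification is
#' monotone non-decreasing in the fold change over
#' loss < neutral < gain < amplified.
#'
#' @param cn_l2fc Numeric vector of copy-number log2 fold changes.
#' @param cfg A [fusion_config()].
#' @return Character vector over
#'   `{"amplified", "gain", "neutral", "loss", "unknown"}`.
#' @export
classify_cn_status <- function(cn_l2fc, cfg = fusion_config()) {
  ifelse(is.na(cn_l2fc), "unknown",
    ifelse(cn_l2fc > cfg$cn_amplified_l2fc, "amplified",
      ifelse(cn_l2fc > cfg$cn_gain_l2fc, "gain",
        ifelse(cn_l2fc < cfg$cn_loss_l2fc, "loss", "neutral"))))
}

#' Fusion burden versus fraction of genome altered
#'
#' Splits patients into high fusion burden (at least
#' `cfg$high_burden_min` high-confidence fusions) versus the rest and
#' compares their fractions of genome altered with a two-sided Wilcoxon
#' rank-sum test, reporting per-group medians and means. With an empty
#' group only the descriptive part is returned (no test).
#'
#' @param burden data.frame with columns `patient_id`, `n_hcf`
#'   (high-confidence fusion count) and `fga`.
#' @param cfg A [fusion_config()].
#' @return List: `n_high, n_low, median_high, median_low, mean_high,
#'   mean_low, p_value` (NA when a group is empty), `method`.
#' @export
burden_vs_fga <- function(burden, cfg = fusion_config()) {
  high <- burden$n_hcf >= cfg$high_burden_min
  fga_h <- burden$fga[high]
  fga_l <- burden$fga[!high]
  out <- list(
    n_high = length(fga_h), n_low = length(fga_l),
    median_high = stats::median(fga_h), median_low = stats::median(fga_l),
    mean_high = mean(fga_h), mean_low = mean(fga_l),
    p_value = NA_real_,
    method = "two-sided Wilcoxon rank-sum"
  )
  if (length(fga_h) >= 1 && length(fga_l) >= 1) {
    wt <- suppressWarnings(
      stats::wilcox.test(fga_h, fga_l, alternative = "two.sided")
    )
    out$p_value <- wt$p.value
  }
  out
}

#' Fraction of genome altered from a copy-number segment table
#'
#' FGA is the fraction of segmented bases whose absolute copy-number log2
#' fold change exceeds the gain threshold.
#'
#' @param segments data.frame with columns `chrom, start, end, l2fc`.
#' @param cfg A [fusion_config()] (`cn_gain_l2fc`).
#' @return Fraction in `[0, 1]`.
#' @export
compute_fga <- function(segments, cfg = fusion_config()) {
  w <- segments$end - segments$start + 1
  altered <- abs(segments$l2fc) > cfg$cn_gain_l2fc
  sum(w[altered]) / sum(w)
}
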