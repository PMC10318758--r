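level_rank <- function(level) {
  match(level, c("intron_exact", "fixed_window", "gene_body", "gene_flank"))
}

#' Match structural variants to one merged fusion prediction
#'
#' For every SV, a support is emitted when one breakend footprint lies in
#' any matching-interval level of the 5' partner and the other breakend in
#' any level of the 3' partner, and both breakend orientations are
#' consistent with the observed chimeric transcript: the 5' partner
#' retains its upstream exons in transcript orientation (so on a
#' plus-strand 5' gene the breakend must retain its left side, flipped on
#' minus strand), and the 3' partner retains its downstream exons. Both
#' assignments of the SV's two breakends to the two genes are tried, as
#' are all per-caller RNA breakpoint pairs in the merged prediction; per
#' SV the best combination -- most specific levels, then smallest summed
#' RNA-DNA distance -- is kept.
#'
#' Interval membership is evaluated with a [GenomicRanges::findOverlaps()]
#' index over the breakend footprints; a brute-force all-pairs scan over
#' SV-by-level combinations gives identical supports (tested property).
#'
#' @param prediction One row of [merge_predictions()] output.
#' @param model A `GeneModel`.
#' @param svs data.frame of normalized SVs from [read_sv_vcf()] (any mix
#'   of callers).
#' @param cfg A [fusion_config()].
#' @return data.frame of supports: `sv_idx, sv_id, caller, level5, level3,
#'   dist5, dist3, orientation_ok, rna_caller`, zero rows when nothing
#'   matches. When a partner gene has no transcript in the model, zero
#'   rows with attribute `reason = "no_transcript"`.
#' @export
match_fusion_to_svs <- function(prediction, model, svs, cfg = fusion_config()) {
  empty <- data.frame(
    sv_idx = integer(0), sv_id = character(0), caller = character(0),
    level5 = character(0), level3 = character(0),
    dist5 = numeric(0), dist3 = numeric(0),
    orientation_ok = logical(0), rna_caller = character(0),
    stringsAsFactors = FALSE
  )
  gene5 <- prediction$gene5_id
  gene3 <- prediction$gene3_id
  if (!gene5 %in% model$genes$gene_id || !gene3 %in% model$genes$gene_id) {
    attr(empty, "reason") <- "no_transcript"
    return(empty)
  }
  if (nrow(svs) == 0) return(empty)

  bps <- prediction$breakpoints[[1]]

  # footprint index over all breakends (2 per SV)
  fp <- GenomicRanges::GRanges(
    seqnames = c(svs$chrom1, svs$chrom2),
    ranges = IRanges::IRanges(
      start = c(svs$fp1_start, svs$fp2_start),
      end = c(svs$fp1_end, svs$fp2_end)
    )
  )
  fp_sv <- rep(seq_len(nrow(svs)), 2L)
  fp_end <- rep(1:2, each = nrow(svs))
  fp_ori <- c(svs$ori1, svs$ori2)
  fp_pos <- c(svs$pos1, svs$pos2)

  best <- list()
  for (b in seq_len(nrow(bps))) {
    mis5 <- derive_matching_intervals(model, gene5, bps$pos5[b],
                                      "five_prime", cfg)
    mis3 <- derive_matching_intervals(model, gene3, bps$pos3[b],
                                      "three_prime", cfg)
    if (!length(mis5$levels) || !length(mis3$levels)) next

    side_hits <- function(mis) {
      sel <- which(as.character(GenomeInfoDb::seqnames(fp)) == mis$chrom)
      if (!length(sel)) return(NULL)
      ov <- GenomicRanges::findOverlaps(fp[sel], mis$levels)
      if (!length(ov)) return(NULL)
      q <- sel[S4Vectors::queryHits(ov)]
      lev <- S4Vectors::mcols(mis$levels)$level[S4Vectors::subjectHits(ov)]
      rk <- level_rank(lev)
      keep <- !duplicated(q[order(q, rk)])
      o <- order(q, rk)[keep]
      ok <- fp_ori[q[o]] == mis$expected_orientation
      data.frame(fp_i = q[o], level = lev[o],
                 dist = abs(fp_pos[q[o]] - mis$rna_breakpoint),
                 ori_ok = ok)
    }
    h5 <- side_hits(mis5)
    h3 <- side_hits(mis3)
    if (is.null(h5) || is.null(h3)) next

    for (i in seq_len(nrow(h5))) {
      for (j in seq_len(nrow(h3))) {
        a <- h5$fp_i[i]; c3 <- h3$fp_i[j]
        if (fp_sv[a] != fp_sv[c3] || fp_end[a] == fp_end[c3]) next
        if (!h5$ori_ok[i] || !h3$ori_ok[j]) next
        sv_i <- fp_sv[a]
        cand <- list(
          sv_idx = sv_i, sv_id = svs$id[sv_i], caller = svs$caller[sv_i],
          level5 = h5$level[i], level3 = h3$level[j],
          dist5 = h5$dist[i], dist3 = h3$dist[j],
          rna_caller = bps$caller[b]
        )
        key <- as.character(sv_i)
        if (is.null(best[[key]]) || better_support(cand, best[[key]])) {
          best[[key]] <- cand
        }
      }
    }
  }
  if (!length(best)) return(empty)
  out <- do.call(rbind, lapply(best, function(s) {
    data.frame(sv_idx = s$sv_idx, sv_id = s$sv_id, caller = s$caller,
               level5 = s$level5, level3 = s$level3,
               dist5 = s$dist5, dist3 = s$dist3,
               orientation_ok = TRUE, rna_caller = s$rna_caller,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sv_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

better_support <- function(a, b) {
  ra <- level_rank(a$level5) + level_rank(a$level3)
  rb <- level_rank(b$level5) + level_rank(b$level3)
  if (ra != rb) return(ra < rb)
  (a$dist5 + a$dist3) < (b$dist5 + b$dist3)
}

#' Reciprocal overlap of two intrachromosomal SV spans
#'
#' The standard SV-equivalence criterion: the overlap length divided by
#' each span's length, taking the minimum of the two fractions; 0 when
#' disjoint. Spans are 1-based inclusive.
#'
#' @param a_start,a_end,b_start,b_end Span coordinates (vectorized).
#' @return Fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
  la <- a_end - a_start + 1
  lb <- b_end - b_start + 1
  pmin(ov / la, ov / lb)
}

# Reciprocal overlap of two SV rows; error on CTX (no span).
sv_reciprocal_overlap <- function(sv_a, sv_b) {
  if (sv_a$sv_type == "CTX" || sv_b$sv_type == "CTX") {
    stop("reciprocal overlap is undefined for interchromosomal SVs; ",
         "use breakend proximity")
  }
  if (sv_a$chrom1 != sv_b$chrom1) return(0)
  reciprocal_overlap(sv_a$pos1, sv_a$pos2, sv_b$pos1, sv_b$pos2)
}

#' Absolute distance between an RNA and a DNA breakpoint
#'
#' @param chrom_rna,pos_rna RNA breakpoint.
#' @param chrom_dna,pos_dna DNA breakend.
#' @return Distance in bp; error when the chromosomes differ.
#' @export
breakpoint_distance <- function(chrom_rna, pos_rna, chrom_dna, pos_dna) {
  if (any(chrom_rna != chrom_dna)) {
    stop("breakpoint distance is undefined across chromosomes")
  }
  abs(pos_rna - pos_dna)
}

#' Classify somatic status from paired tumor/normal allele fractions
#'
#' Normal-sample variant support at or above `germline_normal_af_min`
#' marks a constitutional (germline) variant; otherwise tumor allele
#' fraction at or above `tumor_af_min` marks a tumor-specific variant and
#' anything below is low allele fraction (typically events in highly
#' amplified regions, where many reference reads depress the fraction).
#'
#' @param tumor_af,normal_af Allele fractions in `[0, 1]`; `NA` allowed.
#' @param cfg A [fusion_config()].
#' @return Character vector over `{"tumor_specific", "germline",
#'   "low_af", "unclassified"}` (`"unclassified"` when both fractions are
#'   missing).
#' @export
classify_somatic <- function(tumor_af, normal_af, cfg = fusion_config()) {
  n <- max(length(tumor_af), length(normal_af))
  tumor_af <- rep_len(tumor_af, n)
  normal_af <- rep_len(normal_af, n)
  out <- character(n)
  for (i in seq_len(n)) {
    t <- tumor_af[i]; nf <- normal_af[i]
    out[i] <- if (is.na(t) && is.na(nf)) {
      "unclassified"
    } else if (!is.na(nf) && nf >= cfg$germline_normal_af_min) {
      "germline"
    } else if (!is.na(t) && t >= cfg$tumor_af_min) {
      "tumor_specific"
    } else {
      "low_af"
    }
  }
  out
}

#' Build a multi-caller consensus SV for one fusion
#'
#' Supports are clustered across callers: intrachromosomal calls join a
#' cluster when their reciprocal overlap exceeds `min_recip`;
#' interchromosomal calls when both breakend pairs lie within
#' `ctx_max_dist`. The largest cluster by distinct callers wins (ties:
#' most specific match levels, then smallest summed RNA-DNA distance).
#' Consensus breakend positions and allele fractions are the medians over
#' the clustered calls, robust to a single outlier footprint. A fusion is
#' high confidence when both RNA callers predicted it and at least
#' `min_callers` SV callers support the consensus. The consensus is
#' `composite` when clustered calls disagree on SV type or one caller
#' contributes a multi-call chain. A consensus built solely from calls
#' failing their caller's FILTER is flagged `filtered_only`.
#'
#' @param prediction One row of [merge_predictions()] output.
#' @param supports data.frame from [match_fusion_to_svs()].
#' @param svs The SV data.frame the supports index into.
#' @param cfg A [fusion_config()].
#' @return A one-row data.frame (`ResolvedFusion`) or NULL when there are
#'   no supports: gene pair, consensus breakends, `sv_type, n_sv_callers,
#'   sv_callers, predicted_by_both_rna, high_confidence, composite,
#'   filtered_only, tumor_af, normal_af, somatic_class, level5, level3,
#'   dist5, dist3, max_ffpm, low_expression`.
#' @export
build_consensus <- function(prediction, supports, svs, cfg = fusion_config()) {
  if (is.null(supports) || nrow(supports) == 0) return(NULL)
  sv <- svs[supports$sv_idx, , drop = FALSE]
  m <- nrow(sv)

  # cluster adjacency
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) { adj[i, j] <- TRUE; next }
      if (j < i) { adj[i, j] <- adj[j, i]; next }
      a <- sv[i, ]; b <- sv[j, ]
      linked <- if (a$sv_type == "CTX" && b$sv_type == "CTX") {
        same <- a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2
        same && abs(a$pos1 - b$pos1) <= cfg$ctx_max_dist &&
          abs(a$pos2 - b$pos2) <= cfg$ctx_max_dist
      } else if (a$sv_type != "CTX" && b$sv_type != "CTX") {
        a$chrom1 == b$chrom1 &&
          reciprocal_overlap(a$pos1, a$pos2, b$pos1, b$pos2) > cfg$min_recip
      } else {
        FALSE
      }
      adj[i, j] <- linked
    }
  }
  comp <- connected_components(adj)

  # pick winning cluster: most distinct callers, then most specific
  # levels, then smallest summed RNA-DNA distance
  score <- lapply(unique(comp), function(k) {
    idx <- which(comp == k)
    list(k = k, idx = idx,
         callers = length(unique(sv$caller[idx])),
         rank = sum(level_rank(supports$level5[idx]) +
                    level_rank(supports$level3[idx])) / length(idx),
         dist = sum(supports$dist5[idx] + supports$dist3[idx]) / length(idx))
  })
  ord <- order(-vapply(score, `[[`, 1, "callers"),
               vapply(score, `[[`, 1, "rank"),
               vapply(score, `[[`, 1, "dist"))
  win <- score[[ord[1]]]$idx

  cs <- sv[win, , drop = FALSE]
  sup <- supports[win, , drop = FALSE]
  n_callers <- length(unique(cs$caller))
  types <- unique(cs$sv_type)
  composite <- length(types) > 1 || any(duplicated(cs$caller))
  sv_type <- names(sort(table(cs$sv_type), decreasing = TRUE))[1]
  tumor_af <- stats::median(cs$tumor_af, na.rm = TRUE)
  normal_af <- stats::median(cs$normal_af, na.rm = TRUE)
  if (is.nan(tumor_af)) tumor_af <- NA_real_
  if (is.nan(normal_af)) normal_af <- NA_real_

  best5 <- which.min(level_rank(sup$level5))
  best3 <- which.min(level_rank(sup$level3))

  data.frame(
    gene5_id = prediction$gene5_id, gene3_id = prediction$gene3_id,
    gene5_name = prediction$gene5_name, gene3_name = prediction$gene3_name,
    chrom1 = cs$chrom1[1], pos1 = as.integer(round(stats::median(cs$pos1))),
    chrom2 = cs$chrom2[1], pos2 = as.integer(round(stats::median(cs$pos2))),
    sv_type = sv_type,
    sv_length = if (sv_type == "CTX") NA_real_ else {
      stats::median(abs(cs$pos2 - cs$pos1))
    },
    n_sv_callers = n_callers,
    sv_callers = paste(sort(unique(cs$caller)), collapse = ","),
    predicted_by_both_rna = prediction$predicted_by_both,
    high_confidence = prediction$predicted_by_both &&
      n_callers >= cfg$min_callers,
    composite = composite,
    filtered_only = all(!cs$filter_pass),
    tumor_af = tumor_af, normal_af = normal_af,
    somatic_class = classify_somatic(tumor_af, normal_af, cfg),
    level5 = sup$level5[best5], level3 = sup$level3[best3],
    dist5 = min(sup$dist5), dist3 = min(sup$dist3),
    max_ffpm = prediction$max_ffpm,
    low_expression = prediction$low_expression,
    stringsAsFactors = FALSE
  )
}

connected_components <- function(adj) {
  m <- nrow(adj)
  comp <- rep(NA_integer_, m)
  k <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
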