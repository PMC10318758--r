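#' Read STAR-Fusion-style fusion predictions
#'
#' Parses the tab-separated prediction table of a STAR-Fusion-style RNA
#' fusion caller into normalized prediction records. Composite gene
#' identifiers (`SYMBOL^ENSG...`) are split into symbol and stable id;
#' breakpoints (`chrom:pos:strand`) are split into coordinates; the
#' caller's healthy-chimera annotation (GTEx recurrent / body-map style
#' flags in the `annots` column) is captured as a logical flag.
#'
#' @param path Path to the TSV file (header row required).
#' @param patient_id Patient identifier attached to every record.
#' @return data.frame of fusion predictions, one row per input row, with
#'   columns `patient_id, caller, gene5_id, gene3_id, gene5_name,
#'   gene3_name, chrom5, pos5, strand5, chrom3, pos3, strand3,
#'   junction_reads, spanning_fragments, ffpm, annots, healthy_flag`.
#' @export
read_star_fusion <- function(path, patient_id = "patient") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("#FusionName", "JunctionReadCount", "SpanningFragCount",
                "LeftGene", "LeftBreakpoint", "RightGene", "RightBreakpoint",
                "FFPM")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("STAR-Fusion file '", path, "' lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(empty_predictions())

  left <- split_composite_gene(df$LeftGene)
  right <- split_composite_gene(df$RightGene)
  bp5 <- split_breakpoint(df$LeftBreakpoint)
  bp3 <- split_breakpoint(df$RightBreakpoint)
  annots <- if ("annots" %in% names(df)) df$annots else rep("", nrow(df))

  data.frame(
    patient_id = patient_id,
    caller = "star_fusion",
    gene5_id = left$id, gene3_id = right$id,
    gene5_name = left$name, gene3_name = right$name,
    chrom5 = bp5$chrom, pos5 = bp5$pos, strand5 = bp5$strand,
    chrom3 = bp3$chrom, pos3 = bp3$pos, strand3 = bp3$strand,
    junction_reads = as.integer(df$JunctionReadCount),
    spanning_fragments = as.integer(df$SpanningFragCount),
    ffpm = as.numeric(df$FFPM),
    annots = annots,
    healthy_flag = grepl("GTEx_recurrent|BodyMap|Babiceanu|healthy",
                         annots, ignore.case = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Read FusionCatcher-style fusion predictions
#'
#' Parses the tab-separated prediction table of a FusionCatcher-style RNA
#' fusion caller. This dialect reports gene symbols and Ensembl ids in
#' separate columns, fusion points as `chrom:pos:strand` (strand may be
#' absent; such rows are accepted with missing strand, to be inferred from
#' gene annotation downstream), and junction/spanning read counts but no
#' FFPM: when `total_fragments` is supplied, FFPM is computed with
#' [compute_ffpm()] from the summed supporting reads, otherwise left
#' missing.
#'
#' @param path Path to the TSV file.
#' @param patient_id Patient identifier attached to every record.
#' @param total_fragments Total RNA-seq fragments of the library, or NULL.
#' @return data.frame with the same columns as [read_star_fusion()].
#' @export
read_fusioncatcher <- function(path, patient_id = "patient",
                               total_fragments = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Gene_1_symbol(5end_fusion_partner)",
                "Gene_2_symbol(3end_fusion_partner)",
                "Gene_1_id(5end_fusion_partner)",
                "Gene_2_id(3end_fusion_partner)",
                "Fusion_point_for_gene_1(5end_fusion_partner)",
                "Fusion_point_for_gene_2(3end_fusion_partner)",
                "Spanning_pairs", "Spanning_unique_reads")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("FusionCatcher file '", path, "' lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(empty_predictions())

  bp5 <- split_breakpoint(df[["Fusion_point_for_gene_1(5end_fusion_partner)"]])
  bp3 <- split_breakpoint(df[["Fusion_point_for_gene_2(3end_fusion_partner)"]])
  desc <- if ("Fusion_description" %in% names(df)) {
    df$Fusion_description
  } else {
    rep("", nrow(df))
  }
  spanning <- as.integer(df$Spanning_pairs)
  junction <- as.integer(df$Spanning_unique_reads)
  supporting <- spanning + junction
  ffpm <- if (is.null(total_fragments)) {
    rep(NA_real_, nrow(df))
  } else {
    compute_ffpm(supporting, total_fragments)
  }

  data.frame(
    patient_id = patient_id,
    caller = "fusioncatcher",
    gene5_id = df[["Gene_1_id(5end_fusion_partner)"]],
    gene3_id = df[["Gene_2_id(3end_fusion_partner)"]],
    gene5_name = df[["Gene_1_symbol(5end_fusion_partner)"]],
    gene3_name = df[["Gene_2_symbol(3end_fusion_partner)"]],
    chrom5 = bp5$chrom, pos5 = bp5$pos, strand5 = bp5$strand,
    chrom3 = bp3$chrom, pos3 = bp3$pos, strand3 = bp3$strand,
    junction_reads = junction,
    spanning_fragments = spanning,
    ffpm = ffpm,
    annots = desc,
    healthy_flag = grepl("healthy|banned|1000genomes|gtex|hpa",
                         desc, ignore.case = TRUE),
    stringsAsFactors = FALSE
  )
}

empty_predictions <- function() {
  data.frame(
    patient_id = character(0), caller = character(0),
    gene5_id = character(0), gene3_id = character(0),
    gene5_name = character(0), gene3_name = character(0),
    chrom5 = character(0), pos5 = integer(0), strand5 = character(0),
    chrom3 = character(0), pos3 = integer(0), strand3 = character(0),
    junction_reads = integer(0), spanning_fragments = integer(0),
    ffpm = numeric(0), annots = character(0), healthy_flag = logical(0),
    stringsAsFactors = FALSE
  )
}

# "SYMBOL^ENSG..." -> list(name=, id=); a bare token is used for both.
split_composite_gene <- function(x) {
  has_caret <- grepl("^", x, fixed = TRUE)
  name <- ifelse(has_caret, sub("\\^.*$", "", x), x)
  id <- ifelse(has_caret, sub("^.*\\^", "", x), x)
  list(name = name, id = id)
}

# "chrom:pos[:strand]" -> list(chrom=, pos=, strand=); strand NA if absent.
split_breakpoint <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  list(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    strand = vapply(parts, function(p) {
      if (length(p) >= 3 && p[3] %in% c("+", "-")) p[3] else NA_character_
    }, "")
  )
}

#' Fusion fragments per million total RNA-seq fragments
#'
#' @param supporting_fragments Number of read fragments supporting the
#'   chimeric junction (junction plus spanning evidence).
#' @param total_fragments Total sequenced fragments of the library.
#' @return `supporting_fragments / total_fragments * 1e6`.
#' @export
compute_ffpm <- function(supporting_fragments, total_fragments) {
  if (any(total_fragments <= 0)) stop("total_fragments must be > 0")
  if (any(supporting_fragments < 0)) stop("supporting_fragments must be >= 0")
  supporting_fragments / total_fragments * 1e6
}

#' Merge the predictions of two RNA fusion callers
#'
#' Predictions are matched on the oriented 5'/3' gene pair: `(G1,G2)` and
#' `(G2,G1)` are distinct fusions (reciprocal orientations are biologically
#' different events and kept separate). Stable gene ids are used as keys
#' when available, falling back to gene symbols. All per-caller
#' breakpoints are retained in a list-column -- one genomic SV may later
#' match several slightly different RNA predictions. No FFPM filtering
#' happens here: predictions below `ffpm_threshold` only receive a
#' `low_expression` flag, so that lowly expressed fusions can be rescued
#' by DNA evidence.
#'
#' @param a,b data.frames of predictions from the two callers (either may
#'   be empty).
#' @param ffpm_threshold FFPM below which `low_expression` is flagged.
#' @return data.frame with one row per oriented gene pair: `gene5_id,
#'   gene3_id, gene5_name, gene3_name, predicted_by_both, callers,
#'   max_ffpm, low_expression, healthy_flag`, and a `breakpoints`
#'   list-column holding the per-caller breakpoint/support rows.
#' @export
merge_predictions <- function(a, b, ffpm_threshold = 0.1) {
  all <- rbind(a, b)
  if (nrow(all) == 0) {
    out <- data.frame(
      gene5_id = character(0), gene3_id = character(0),
      gene5_name = character(0), gene3_name = character(0),
      predicted_by_both = logical(0), callers = character(0),
      max_ffpm = numeric(0), low_expression = logical(0),
      healthy_flag = logical(0), stringsAsFactors = FALSE
    )
    out$breakpoints <- list()
    return(out)
  }

  key5 <- ifelse(!is.na(all$gene5_id) & nzchar(all$gene5_id),
                 all$gene5_id, all$gene5_name)
  key3 <- ifelse(!is.na(all$gene3_id) & nzchar(all$gene3_id),
                 all$gene3_id, all$gene3_name)
  key <- paste(key5, key3, sep = "\r")

  idx <- split(seq_len(nrow(all)), key)
  # deterministic output order: first appearance in the concatenated input
  idx <- idx[order(vapply(idx, min, 1L))]

  rows <- lapply(idx, function(i) {
    sub <- all[i, , drop = FALSE]
    ffpm_known <- sub$ffpm[!is.na(sub$ffpm)]
    max_ffpm <- if (length(ffpm_known)) max(ffpm_known) else NA_real_
    data.frame(
      gene5_id = sub$gene5_id[1], gene3_id = sub$gene3_id[1],
      gene5_name = sub$gene5_name[1], gene3_name = sub$gene3_name[1],
      predicted_by_both = length(unique(sub$caller)) >= 2,
      callers = paste(sort(unique(sub$caller)), collapse = ","),
      max_ffpm = max_ffpm,
      low_expression = is.na(max_ffpm) || max_ffpm < ffpm_threshold,
      healthy_flag = any(sub$healthy_flag),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$breakpoints <- lapply(idx, function(i) {
    all[i, c("caller", "chrom5", "pos5", "strand5", "chrom3", "pos3",
             "strand3", "junction_reads", "spanning_fragments", "ffpm"),
        drop = FALSE]
  })
  out
}
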