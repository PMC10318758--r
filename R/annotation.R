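#' Load annotation resources from plain tables
#'
#' All resources are plain TSVs so that licensed databases are never
#' redistributed; the package ships only tiny synthetic excerpts for
#' testing. Paths set to NULL yield empty resources (all annotations then
#' come back negative).
#'
#' @param healthy_chimera,cancer_chimera Two-column TSVs (`gene5, gene3`)
#'   of chimera gene pairs observed in healthy tissue / cancer databases.
#'   Pairs are stored orientation-sensitively.
#' @param population_svs BED-like TSV (`chrom, start, end, sv_type`) of
#'   common population SVs.
#' @param repeats BED-like TSV (`chrom, start, end, repeat_class,
#'   repeat_family, bp_missing`) of repeat elements. At load time the
#'   track is pre-filtered to classes LINE/SINE/LTR and by completeness
#'   (see `cfg$repeat_completeness_mode`): spurious hits from fragmentary
#'   elements are excluded before any annotation happens.
#' @param segdups BED-like TSV (`chrom, start, end`) of segmental
#'   duplications.
#' @param gene_lists TSV (`gene, category`) with categories among
#'   `oncogene, tsg, kinase, clinically_relevant` (a gene may appear in
#'   several rows).
#' @param cfg A [fusion_config()].
#' @return An `AnnotationResources` list: `healthy_chimera`,
#'   `cancer_chimera` (data.frames), `population_svs`, `repeats`,
#'   `segdups` (`GRanges`), `gene_lists` (data.frame).
#' @export
load_annotation_resources <- function(healthy_chimera = NULL,
                                      cancer_chimera = NULL,
                                      population_svs = NULL,
                                      repeats = NULL,
                                      segdups = NULL,
                                      gene_lists = NULL,
                                      cfg = fusion_config()) {
  read_pairs <- function(path) {
    if (is.null(path)) {
      return(data.frame(gene5 = character(0), gene3 = character(0)))
    }
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("gene5", "gene3")
    df[, 1:2]
  }
  read_intervals <- function(path, extra = character(0)) {
    if (is.null(path)) return(GenomicRanges::GRanges())
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
      seqnames = sub("^chr", "", df[[1]]),
      ranges = IRanges::IRanges(start = df[[2]], end = df[[3]])
    )
    for (col in extra) {
      if (col %in% names(df)) S4Vectors::mcols(gr)[[col]] <- df[[col]]
    }
    gr
  }

  reps <- read_intervals(repeats, c("repeat_class", "repeat_family", "bp_missing"))
  if (length(reps)) {
    keep <- S4Vectors::mcols(reps)$repeat_class %in% c("LINE", "SINE", "LTR")
    bm <- S4Vectors::mcols(reps)$bp_missing
    if (!is.null(bm)) {
      keep <- keep & if (cfg$repeat_completeness_mode == "max_remaining") {
        bm < cfg$repeat_completeness_bp
      } else {
        bm >= cfg$repeat_completeness_bp
      }
    }
    reps <- reps[keep]
  }

  gl <- if (is.null(gene_lists)) {
    data.frame(gene = character(0), category = character(0))
  } else {
    df <- utils::read.delim(gene_lists, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("gene", "category")
    df[, 1:2]
  }

  structure(
    list(
      healthy_chimera = read_pairs(healthy_chimera),
      cancer_chimera = read_pairs(cancer_chimera),
      population_svs = read_intervals(population_svs, "sv_type"),
      repeats = reps,
      segdups = read_intervals(segdups),
      gene_lists = gl
    ),
    class = "AnnotationResources"
  )
}

pair_in_list <- function(g5, g3, pairs, symmetric = FALSE) {
  if (nrow(pairs) == 0) return(FALSE)
  hit <- any(pairs$gene5 == g5 & pairs$gene3 == g3)
  if (symmetric) hit <- hit || any(pairs$gene5 == g3 & pairs$gene3 == g5)
  hit
}

#' Flag a fusion against healthy/cancer chimera gene-pair lists
#'
#' Membership is by exact oriented gene pair (symbols); symmetric
#' matching is off by default since the 5'/3' order is part of the event
#' identity. The RNA caller's own healthy-chimera flag is propagated.
#'
#' @param gene5_name,gene3_name Partner gene symbols.
#' @param res An `AnnotationResources`.
#' @param caller_healthy_flag Healthy-chimera flag reported by the RNA
#'   caller for this prediction.
#' @param symmetric Also match the reversed pair.
#' @return Named logical vector `c(healthy_chimera=, cancer_chimera=)`.
#' @export
annotate_chimera <- function(gene5_name, gene3_name, res,
                             caller_healthy_flag = FALSE,
                             symmetric = FALSE) {
  c(
    healthy_chimera = pair_in_list(gene5_name, gene3_name,
                                   res$healthy_chimera, symmetric) ||
      isTRUE(caller_healthy_flag),
    cancer_chimera = pair_in_list(gene5_name, gene3_name,
                                  res$cancer_chimera, symmetric)
  )
}

#' Does a fusion's consensus SV match a common population SV?
#'
#' True when any population SV has more than 50% reciprocal overlap with
#' the consensus span. Interchromosomal translocations have no span and
#' never match. By default the population SV must be of a compatible type
#' (DEL with DEL/loss, DUP with DUP/gain, INV with INV): a deletion
#' overlapping a common duplication is not the same variant.
#'
#' @param fusion One `ResolvedFusion` row.
#' @param res An `AnnotationResources`.
#' @param cfg A [fusion_config()] (`min_recip`, `popsv_type_aware`).
#' @return Logical scalar.
#' @export
annotate_population_sv <- function(fusion, res, cfg = fusion_config()) {
  if (fusion$sv_type == "CTX" || length(res$population_svs) == 0) return(FALSE)
  pop <- res$population_svs
  same_chrom <- as.character(GenomeInfoDb::seqnames(pop)) == fusion$chrom1
  if (cfg$popsv_type_aware && !is.null(S4Vectors::mcols(pop)$sv_type)) {
    compat <- list(DEL = c("DEL", "loss"), DUP = c("DUP", "gain"),
                   INV = "INV")[[fusion$sv_type]]
    same_chrom <- same_chrom & S4Vectors::mcols(pop)$sv_type %in% compat
  }
  pop <- pop[same_chrom]
  if (!length(pop)) return(FALSE)
  ro <- reciprocal_overlap(fusion$pos1, fusion$pos2,
                           BiocGenerics::start(pop), BiocGenerics::end(pop))
  any(ro > cfg$min_recip)
}

#' Repeat and segmental-duplication hits at a fusion's breakends
#'
#' Each consensus breakend is overlapped against the (pre-filtered)
#' repeat track and the segmental-duplication track.
#'
#' @param fusion One `ResolvedFusion` row.
#' @param res An `AnnotationResources`.
#' @return List with `repeat5`, `repeat3` (comma-joined repeat classes,
#'   `""` when none) and `segdup5`, `segdup3` (logicals).
#' @export
annotate_repeats <- function(fusion, res) {
  hit_classes <- function(chrom, pos) {
    sel <- as.character(GenomeInfoDb::seqnames(res$repeats)) == chrom
    if (!any(sel)) return("")
    reps <- res$repeats[sel]
    ov <- IRanges::overlapsAny(IRanges::ranges(reps),
                               IRanges::IRanges(pos, pos))
    cls <- unique(S4Vectors::mcols(reps)$repeat_class[ov])
    paste(sort(cls), collapse = ",")
  }
  hit_segdup <- function(chrom, pos) {
    sel <- as.character(GenomeInfoDb::seqnames(res$segdups)) == chrom
    if (!any(sel)) return(FALSE)
    any(IRanges::overlapsAny(IRanges::ranges(res$segdups[sel]),
                             IRanges::IRanges(pos, pos)))
  }
  list(
    repeat5 = hit_classes(fusion$chrom1, fusion$pos1),
    repeat3 = hit_classes(fusion$chrom2, fusion$pos2),
    segdup5 = hit_segdup(fusion$chrom1, fusion$pos1),
    segdup3 = hit_segdup(fusion$chrom2, fusion$pos2)
  )
}

#' Cancer-gene flags for the two fusion partners
#'
#' @param gene5_name,gene3_name Partner gene symbols.
#' @param res An `AnnotationResources`.
#' @return Named logical vector: `onco5, tsg5, kinase5, clin5, onco3,
#'   tsg3, kinase3, clin3, onco_or_tsg`.
#' @export
annotate_cancer_genes <- function(gene5_name, gene3_name, res) {
  gl <- res$gene_lists
  has <- function(g, cat) any(gl$gene == g & gl$category == cat)
  out <- c(
    onco5 = has(gene5_name, "oncogene"), tsg5 = has(gene5_name, "tsg"),
    kinase5 = has(gene5_name, "kinase"),
    clin5 = has(gene5_name, "clinically_relevant"),
    onco3 = has(gene3_name, "oncogene"), tsg3 = has(gene3_name, "tsg"),
    kinase3 = has(gene3_name, "kinase"),
    clin3 = has(gene3_name, "clinically_relevant")
  )
  c(out, onco_or_tsg = out[["onco5"]] || out[["tsg5"]] ||
      out[["onco3"]] || out[["tsg3"]])
}

#' Annotate a table of resolved fusions
#'
#' Applies all annotation operations and appends the flags as columns.
#' Annotation is pure decoration: it never changes `somatic_class` or
#' `high_confidence`.
#'
#' @param fusions data.frame of `ResolvedFusion` rows.
#' @param res An `AnnotationResources`.
#' @param caller_healthy_flags Optional logical vector (per row) of the
#'   RNA caller's healthy-chimera flags.
#' @param cfg A [fusion_config()].
#' @return `fusions` with annotation columns added.
#' @export
annotate_fusions <- function(fusions, res, caller_healthy_flags = NULL,
                             cfg = fusion_config()) {
  n <- nrow(fusions)
  if (is.null(caller_healthy_flags)) caller_healthy_flags <- rep(FALSE, n)
  cols <- lapply(seq_len(n), function(i) {
    f <- fusions[i, , drop = FALSE]
    ch <- annotate_chimera(f$gene5_name, f$gene3_name, res,
                           caller_healthy_flags[i], cfg$symmetric_chimera)
    cg <- annotate_cancer_genes(f$gene5_name, f$gene3_name, res)
    rp <- annotate_repeats(f, res)
    data.frame(
      healthy_chimera = ch[["healthy_chimera"]],
      cancer_chimera = ch[["cancer_chimera"]],
      population_sv = annotate_population_sv(f, res, cfg),
      repeat5 = rp$repeat5, repeat3 = rp$repeat3,
      segdup5 = rp$segdup5, segdup3 = rp$segdup3,
      onco5 = cg[["onco5"]], tsg5 = cg[["tsg5"]], kinase5 = cg[["kinase5"]],
      onco3 = cg[["onco3"]], tsg3 = cg[["tsg3"]], kinase3 = cg[["kinase3"]],
      clinically_relevant = cg[["clin5"]] || cg[["clin3"]],
      onco_or_tsg = cg[["onco_or_tsg"]],
      stringsAsFactors = FALSE
    )
  })
  cbind(fusions, do.call(rbind, cols))
}

#' Map per-patient fusions to distinct fusions with recurrence counts
#'
#' Groups resolved fusions across patients by oriented gene pair, counts
#' the patients carrying each, and reports the majority somatic class
#' (ties and disagreements flagged). The sum of recurrence counts equals
#' the number of input fusions.
#'
#' @param fusions data.frame of resolved fusions from several patients;
#'   must carry a `patient_id` column.
#' @return data.frame: `gene5_name, gene3_name, recurrence, n_patients,
#'   somatic_class, class_conflict, high_confidence_any`.
#' @export
map_to_distinct <- function(fusions) {
  if (nrow(fusions) == 0) {
    return(data.frame(gene5_name = character(0), gene3_name = character(0),
                      recurrence = integer(0), n_patients = integer(0),
                      somatic_class = character(0),
                      class_conflict = logical(0),
                      high_confidence_any = logical(0)))
  }
  key <- paste(fusions$gene5_name, fusions$gene3_name, sep = "\r")
  idx <- split(seq_len(nrow(fusions)), key)
  idx <- idx[order(vapply(idx, min, 1L))]
  out <- do.call(rbind, lapply(idx, function(i) {
    sub <- fusions[i, , drop = FALSE]
    tab <- sort(table(sub$somatic_class), decreasing = TRUE)
    data.frame(
      gene5_name = sub$gene5_name[1], gene3_name = sub$gene3_name[1],
      recurrence = length(i),
      n_patients = length(unique(sub$patient_id)),
      somatic_class = names(tab)[1],
      class_conflict = length(tab) > 1,
      high_confidence_any = any(sub$high_confidence),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
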