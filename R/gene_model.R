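#' Parse a Gencode-dialect GTF into a gene model
#'
#' Reads gene annotation with [rtracklayer::import()] and assembles, per
#' transcript, its exon structure, tags (including repeated `tag`
#' attributes, which plain GTF importers collapse), transcript support
#' level, biotype and coding-sequence length. Genes whose transcripts carry
#' no exons are dropped with a warning.
#'
#' @param path Path to a GTF file with `gene`/`transcript`/`exon` (and
#'   optionally `CDS`) features and Gencode-style attributes
#'   (`gene_id`, `transcript_id`, `tag`, `transcript_support_level`).
#' @return A `GeneModel` object: a list with
#'   \describe{
#'     \item{transcripts}{data.frame, one row per transcript: ids, names,
#'       chrom, strand, span, biotype, `tsl`, `cds_length`, and a `tags`
#'       list-column.}
#'     \item{exons}{named list of `GRanges`, one per transcript, sorted by
#'       genomic start.}
#'     \item{genes}{data.frame, one row per gene, with the canonical
#'       transcript chosen by [select_canonical()].}
#'   }
#' @seealso [select_canonical()], [derive_matching_intervals()]
#' @export
parse_gtf <- function(path) {
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)

  is_tx <- mc$type == "transcript"
  is_ex <- mc$type == "exon"
  if (!any(is_tx) || !any(is_ex)) {
    stop("GTF '", path, "' contains no transcript/exon features")
  }

  # rtracklayer keeps only the last of repeated 'tag' attributes; recover
  # the full tag set with a targeted scan of the transcript lines.
  tags_by_tx <- scan_gtf_tags(path)

  tx_id <- mc$transcript_id[is_tx]
  tsl_raw <- if ("transcript_support_level" %in% names(mc)) {
    mc$transcript_support_level[is_tx]
  } else {
    rep(NA_character_, sum(is_tx))
  }
  biotype <- if ("transcript_type" %in% names(mc)) {
    mc$transcript_type[is_tx]
  } else if ("transcript_biotype" %in% names(mc)) {
    mc$transcript_biotype[is_tx]
  } else {
    rep(NA_character_, sum(is_tx))
  }

  transcripts <- data.frame(
    transcript_id = tx_id,
    gene_id = mc$gene_id[is_tx],
    gene_name = if ("gene_name" %in% names(mc)) mc$gene_name[is_tx] else mc$gene_id[is_tx],
    chrom = as.character(GenomeInfoDb::seqnames(gr)[is_tx]),
    strand = as.character(BiocGenerics::strand(gr)[is_tx]),
    tx_start = BiocGenerics::start(gr)[is_tx],
    tx_end = BiocGenerics::end(gr)[is_tx],
    biotype = biotype,
    tsl = suppressWarnings(as.integer(tsl_raw)),
    stringsAsFactors = FALSE
  )
  transcripts$tags <- I(lapply(tx_id, function(id) {
    tg <- tags_by_tx[[id]]
    if (is.null(tg)) character(0) else tg
  }))

  ex <- gr[is_ex]
  exons <- split(ex, S4Vectors::mcols(ex)$transcript_id)
  exons <- lapply(exons, function(e) BiocGenerics::sort(e, ignore.strand = TRUE))

  # CDS length per transcript (0 when no CDS features)
  is_cds <- mc$type == "CDS"
  cds_len <- integer(nrow(transcripts))
  names(cds_len) <- transcripts$transcript_id
  if (any(is_cds)) {
    cds <- gr[is_cds]
    by_tx <- tapply(BiocGenerics::width(cds), S4Vectors::mcols(cds)$transcript_id, sum)
    cds_len[names(by_tx)] <- as.integer(by_tx)
  }
  transcripts$cds_length <- unname(cds_len[transcripts$transcript_id])

  has_exons <- transcripts$transcript_id %in% names(exons)
  transcripts <- transcripts[has_exons, , drop = FALSE]
  exonless_genes <- setdiff(unique(mc$gene_id[is_tx | mc$type == "gene"]),
                            unique(transcripts$gene_id))
  if (length(exonless_genes)) {
    warning("dropping ", length(exonless_genes),
            " gene(s) without exon-bearing transcripts: ",
            paste(utils::head(exonless_genes, 5), collapse = ", "))
  }

  model <- structure(
    list(transcripts = transcripts, exons = exons[transcripts$transcript_id]),
    class = "GeneModel"
  )
  model$genes <- build_gene_table(model)
  model
}

# Pre-validation pass: field count, coordinate sanity, attribute syntax.
# Errors name the offending 1-based line number; records with unknown
# strand are reported (the caller skips them via rtracklayer's import of
# the full file -- strand '.' becomes '*' and such transcripts are dropped
# downstream).
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  bad_strand <- integer(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GTF record at line ", i, ": expected 9 tab-separated fields")
    }
    st <- suppressWarnings(as.integer(f[4]))
    en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en)) {
      stop("malformed GTF record at line ", i, ": non-numeric coordinates")
    }
    if (en < st) {
      stop("malformed GTF record at line ", i, ": end (", en,
           ") < start (", st, ")")
    }
    if (!grepl("\\w+ \"[^\"]*\"", f[9]) && !grepl("\\w+ [^;]+;", f[9])) {
      stop("malformed GTF attribute column at line ", i)
    }
    if (!f[7] %in% c("+", "-")) bad_strand <- c(bad_strand, i)
  }
  if (length(bad_strand)) {
    warning("skipping ", length(bad_strand),
            " record(s) with unknown strand (lines ",
            paste(utils::head(bad_strand, 5), collapse = ", "), ")")
  }
  invisible(TRUE)
}

# Collect all 'tag "..."' values per transcript from raw GTF text.
scan_gtf_tags <- function(path) {
  lines <- readLines(path)
  keep <- grepl("\ttranscript\t", lines, fixed = TRUE)
  out <- list()
  for (ln in lines[keep]) {
    id <- sub('.*transcript_id "([^"]+)".*', "\\1", ln)
    m <- gregexpr('tag "([^"]+)"', ln)[[1]]
    if (m[1] == -1) {
      out[[id]] <- character(0)
    } else {
      tags <- regmatches(ln, gregexpr('tag "([^"]+)"', ln))[[1]]
      out[[id]] <- sub('tag "([^"]+)"', "\\1", tags)
    }
  }
  out
}

build_gene_table <- function(model) {
  tx <- model$transcripts
  genes <- unique(tx[, c("gene_id", "gene_name", "chrom", "strand")])
  genes$start <- vapply(genes$gene_id, function(g) {
    min(tx$tx_start[tx$gene_id == g])
  }, integer(1))
  genes$end <- vapply(genes$gene_id, function(g) {
    max(tx$tx_end[tx$gene_id == g])
  }, integer(1))
  genes$canonical_transcript <- vapply(genes$gene_id, function(g) {
    select_canonical(tx[tx$gene_id == g, , drop = FALSE])$transcript_id
  }, character(1))
  rownames(genes) <- NULL
  genes
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts on", length(unique(x$genes$chrom)), "contigs\n")
  invisible(x)
}

#' Select the canonical transcript of a gene
#'
#' Applies stepwise filters, each retained only when at least one
#' transcript survives it, until a single transcript remains:
#' MANE Select tag; `basic` tag; `CCDS` tag; an APPRIS principal tag;
#' protein-coding biotype; best (minimum) transcript support level, with
#' missing TSL ranking worst; longest coding sequence. Remaining ties are
#' broken by the lexicographically smallest transcript id, making the
#' choice deterministic and independent of input order.
#'
#' @param transcripts data.frame of the transcripts of one gene, as stored
#'   in a `GeneModel` (must have `tags` list-column, `biotype`, `tsl`,
#'   `cds_length`, `transcript_id`).
#' @return The single selected transcript row (data.frame of one row).
#' @export
select_canonical <- function(transcripts) {
  stopifnot(nrow(transcripts) >= 1)
  cand <- transcripts

  apply_filter <- function(cand, keep) {
    if (any(keep)) cand[keep, , drop = FALSE] else cand
  }
  has_tag <- function(cand, tag) {
    vapply(cand$tags, function(t) tag %in% t, logical(1))
  }

  cand <- apply_filter(cand, has_tag(cand, "MANE_Select"))
  cand <- apply_filter(cand, has_tag(cand, "basic"))
  cand <- apply_filter(cand, has_tag(cand, "CCDS"))
  cand <- apply_filter(cand, vapply(cand$tags, function(t) {
    any(startsWith(t, "appris_principal"))
  }, logical(1)))
  cand <- apply_filter(cand, !is.na(cand$biotype) & cand$biotype == "protein_coding")

  tsl <- ifelse(is.na(cand$tsl), Inf, cand$tsl)
  cand <- apply_filter(cand, tsl == min(tsl))
  cand <- apply_filter(cand, cand$cds_length == max(cand$cds_length))

  cand[order(cand$transcript_id)[1], , drop = FALSE]
}

#' Derive the genomic matching-interval hierarchy for an RNA breakpoint
#'
#' Given the canonical transcript of a fusion partner gene and the RNA
#' breakpoint of a predicted chimeric transcript, derives the genomic
#' intervals in which the corresponding DNA breakend must lie, ordered
#' from most to least specific:
#' \describe{
#'   \item{intron_exact}{When the RNA breakpoint coincides (within
#'     `cfg$exon_boundary_tolerance_bp`) with the splice boundary expected
#'     for its side -- for the 5' partner the transcript-orientation end of
#'     an exon, for the 3' partner the transcript-orientation start -- the
#'     interval spans from that boundary across the adjacent intron to the
#'     next exon boundary, on the side where the DNA break must lie for
#'     the observed transcript. For minus-strand genes the genomic
#'     direction flips. A breakpoint not at a boundary degrades this level
#'     to a `cfg$noncanonical_window_bp` window around the breakpoint,
#'     flagged non-canonical.}
#'   \item{gene_body}{The full transcript span.}
#'   \item{gene_flank}{The transcript span extended by `cfg$flank_bp`.}
#' }
#' In `interval_mode = "fixed_window"` a single level `fixed_window` of
#' total size `cfg$fixed_window_bp` centered on the RNA breakpoint is
#' returned instead (a comparison baseline, not gene-structure aware).
#'
#' @param model A `GeneModel`.
#' @param gene_id Gene identifier of the fusion partner.
#' @param rna_pos 1-based genomic position of the RNA breakpoint (on the
#'   gene's chromosome).
#' @param side `"five_prime"` or `"three_prime"`: which fusion partner this
#'   gene is. The 5' partner retains its upstream exons in transcript
#'   orientation, so its DNA break lies downstream of the last retained
#'   exon; the 3' partner retains downstream exons, so its break lies
#'   upstream of the first retained exon.
#' @param cfg A [fusion_config()].
#' @return A `MatchIntervalSet`: list with `gene_id`, `side`,
#'   `transcript_id`, `strand`, `levels` (a `GRanges` with a `level`
#'   metadata column, most specific first), `rna_breakpoint`,
#'   `canonical_boundary` (did the breakpoint hit an exon boundary),
#'   `expected_orientation` (breakend side that must be retained:
#'   `"left"`/`"right"`), and `reason` (`NA` or a reason code when
#'   `levels` is empty, e.g. `"outside_gene_flank"`).
#' @export
derive_matching_intervals <- function(model, gene_id, rna_pos,
                                      side = c("five_prime", "three_prime"),
                                      cfg = fusion_config()) {
  side <- match.arg(side)
  g <- model$genes[model$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("gene '", gene_id, "' not in model")
  tx_id <- g$canonical_transcript
  tx <- model$transcripts[model$transcripts$transcript_id == tx_id, , drop = FALSE]
  ex <- model$exons[[tx_id]]
  strand <- tx$strand
  chrom <- tx$chrom

  # expected retained side of the matching DNA breakend
  expected_ori <- if (side == "five_prime") {
    if (strand == "+") "left" else "right"
  } else {
    if (strand == "+") "right" else "left"
  }

  res <- structure(
    list(gene_id = gene_id, side = side, transcript_id = tx_id,
         strand = strand, chrom = chrom, rna_breakpoint = rna_pos,
         canonical_boundary = FALSE, expected_orientation = expected_ori,
         levels = GenomicRanges::GRanges(), reason = NA_character_),
    class = "MatchIntervalSet"
  )

  body_start <- tx$tx_start
  body_end <- tx$tx_end
  flank_start <- max(1L, body_start - cfg$flank_bp)
  flank_end <- body_end + cfg$flank_bp

  if (rna_pos < flank_start || rna_pos > flank_end) {
    res$reason <- "outside_gene_flank"
    return(res)
  }

  if (cfg$interval_mode == "fixed_window") {
    half <- cfg$fixed_window_bp %/% 2L
    res$levels <- level_granges(chrom,
                                starts = max(1L, rna_pos - half),
                                ends = rna_pos + half,
                                levels = "fixed_window")
    return(res)
  }

  starts <- BiocGenerics::start(ex)
  ends <- BiocGenerics::end(ex)
  n <- length(ex)
  tol <- cfg$exon_boundary_tolerance_bp

  # transcript-orientation order of exons: index 1 = 5'-most exon
  tx_order <- if (strand == "+") seq_len(n) else rev(seq_len(n))

  # boundary coordinate that the RNA breakpoint should hit:
  # 5' partner -> transcript-orientation END of a retained exon
  # 3' partner -> transcript-orientation START of a retained exon
  boundary_of <- function(i) {
    if (side == "five_prime") {
      if (strand == "+") ends[i] else starts[i]
    } else {
      if (strand == "+") starts[i] else ends[i]
    }
  }

  hit <- NA_integer_  # genomic exon index whose boundary matches
  for (i in seq_len(n)) {
    if (abs(boundary_of(i) - rna_pos) <= tol) { hit <- i; break }
  }

  l1 <- NULL
  if (!is.na(hit)) {
    k_tx <- match(hit, tx_order)  # position in transcript orientation
    if (side == "five_prime") {
      # break lies in the intron following exon k (transcript orientation)
      if (k_tx < n) {
        nxt <- tx_order[k_tx + 1L]
        l1 <- range(boundary_of(hit),
                    if (strand == "+") starts[nxt] else ends[nxt])
      }
    } else {
      # break lies in the intron preceding exon k (transcript orientation)
      if (k_tx > 1L) {
        prv <- tx_order[k_tx - 1L]
        l1 <- range(boundary_of(hit),
                    if (strand == "+") ends[prv] else starts[prv])
      }
    }
    # keep the intronic bases only: the flanking exon-boundary bases
    # themselves are exonic and are excluded
    if (!is.null(l1)) l1 <- c(l1[1] + 1, l1[2] - 1)
    if (!is.null(l1) && l1[1] > l1[2]) l1 <- NULL  # zero-length intron
  }
  res$canonical_boundary <- !is.null(l1)
  if (is.null(l1)) {
    # non-canonical breakpoint (or boundary of a terminal exon): fall back
    # to a window around the breakpoint, clipped to the transcript span so
    # the level nesting invariant holds
    w <- cfg$noncanonical_window_bp
    l1 <- c(max(body_start, rna_pos - w), min(body_end, rna_pos + w))
    if (l1[1] > l1[2]) l1 <- NULL  # breakpoint outside gene body entirely
  }

  starts_v <- c(if (!is.null(l1)) l1[1], body_start, flank_start)
  ends_v <- c(if (!is.null(l1)) l1[2], body_end, flank_end)
  levels_v <- c(if (!is.null(l1)) "intron_exact", "gene_body", "gene_flank")
  res$levels <- level_granges(chrom, starts_v, ends_v, levels_v)
  res
}

level_granges <- function(chrom, starts, ends, levels) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts, end = ends)
  )
  S4Vectors::mcols(gr)$level <- levels
  gr
}

#' @export
print.MatchIntervalSet <- function(x, ...) {
  cat(sprintf("MatchIntervalSet %s (%s, %s strand) rna_bp=%d%s\n",
              x$gene_id, x$side, x$strand, x$rna_breakpoint,
              if (!is.na(x$reason)) paste0(" [", x$reason, "]") else ""))
  if (length(x$levels)) {
    df <- as.data.frame(x$levels)
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-12s %s:%d-%d\n", df$level[i], df$seqnames[i],
                  df$start[i], df$end[i]))
    }
  }
  invisible(x)
}
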