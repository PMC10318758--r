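#' Per-caller FORMAT-field adapters
#'
#' Each SV caller reports variant- and reference-supporting reads under
#' different FORMAT keys. The adapter table maps a dialect name to a
#' function that, given the parsed FORMAT key/value pairs of one sample,
#' returns `c(variant, reference)` read counts. Variant evidence is the
#' sum of paired-end and split-read support; reference evidence likewise.
#'
#' \describe{
#'   \item{manta}{`PR` (ref,var paired reads) + `SR` (ref,var split reads).}
#'   \item{delly}{`DV` + `RV` variant pairs/junction reads vs `DR` + `RR`.}
#'   \item{gridss}{`VF` variant fragments vs `REF` + `REFPAIR`.}
#'   \item{generic}{`VR` variant reads vs `RR` reference reads (used by
#'     [write_sv_vcf()] round trips).}
#' }
#'
#' @return Named list of adapter functions.
#' @export
sv_dialects <- function() {
  take <- function(fields, key, i = 1) {
    v <- fields[[key]]
    if (is.null(v) || is.na(v[i])) 0L else as.integer(v[i])
  }
  list(
    manta = function(f) {
      c(take(f, "PR", 2) + take(f, "SR", 2),
        take(f, "PR", 1) + take(f, "SR", 1))
    },
    delly = function(f) {
      c(take(f, "DV") + take(f, "RV"),
        take(f, "DR") + take(f, "RR"))
    },
    gridss = function(f) {
      c(take(f, "VF"),
        take(f, "REF") + take(f, "REFPAIR"))
    },
    generic = function(f) {
      c(take(f, "VR"), take(f, "RR"))
    }
  )
}

#' Read a structural-variant VCF into normalized records
#'
#' Handles both symbolic records (`<DEL>`, `<DUP>`, `<INV>` with `END`)
#' and breakend (`BND`) records paired via `MATEID`. Breakend mates are
#' joined into one record; unmatched mates and single-breakend records
#' (no mate, e.g. GRIDSS `.`-terminated ALTs) are dropped with a warning
#' since they cannot link two genes. `CIPOS`/`CIEND` become breakend
#' footprints (default: the precise position). Records failing the caller
#' FILTER are retained and flagged -- consensus building decides their
#' fate, not the reader. Chromosome names are harmonized by stripping a
#' `chr` prefix.
#'
#' @param path VCF 4.2 file.
#' @param dialect One of `names(sv_dialects())`; selects the FORMAT
#'   adapter used to extract tumor/normal read support.
#' @param tumor_sample,normal_sample Sample column names; when absent from
#'   the VCF the first column is taken as normal and the second as tumor.
#' @return data.frame with one row per SV: `caller, id, chrom1, pos1,
#'   ori1, fp1_start, fp1_end, chrom2, pos2, ori2, fp2_start, fp2_end,
#'   sv_type, length, tumor_var, tumor_ref, normal_var, normal_ref,
#'   tumor_af, normal_af, filter_status, filter_pass`. Orientation
#'   `"left"`/`"right"` names the side of the position retained in the
#'   derived allele. `bnd1 <= bnd2` in genome order for intrachromosomal
#'   records.
#' @export
read_sv_vcf <- function(path, dialect = c("manta", "delly", "gridss", "generic"),
                        tumor_sample = "TUMOR", normal_sample = "NORMAL") {
  dialect <- match.arg(dialect)
  adapter <- sv_dialects()[[dialect]]
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) return(empty_svs(dialect))
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(empty_svs(dialect))

  gt <- v@gt
  samples <- colnames(gt)[-1]
  t_col <- if (tumor_sample %in% samples) tumor_sample else samples[min(2, length(samples))]
  n_col <- if (normal_sample %in% samples) normal_sample else samples[1]

  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info,
                                  perl = TRUE))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  parse_fmt <- function(i, col) {
    keys <- strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    vals <- strsplit(gt[i, col], ":", fixed = TRUE)[[1]]
    stats::setNames(lapply(vals, function(x) {
      suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
    }), keys[seq_along(vals)])
  }
  ci_of <- function(info, key, pos) {
    ci <- info_get(info, key)
    if (is.na(ci)) return(c(pos, pos))
    d <- as.integer(strsplit(ci, ",", fixed = TRUE)[[1]])
    c(pos + d[1], pos + d[2])
  }
  norm_chrom <- function(x) sub("^chr", "", x)

  recs <- list()
  seen_mates <- character(0)
  ids <- fix[, "ID"]

  for (i in seq_len(n)) {
    alt <- fix[i, "ALT"]
    info <- fix[i, "INFO"]
    id <- ids[i]
    chrom <- norm_chrom(fix[i, "CHROM"])
    pos <- as.integer(fix[i, "POS"])
    filt <- fix[i, "FILTER"]
    if (is.na(filt) || filt == ".") filt <- "PASS"

    tc <- adapter(parse_fmt(i, t_col))
    nc <- adapter(parse_fmt(i, n_col))

    if (grepl("^<(DEL|DUP|INV)>$", alt)) {
      type <- sub("^<|>$", "", gsub("[<>]", "", alt))
      end <- as.integer(info_get(info, "END"))
      ori <- switch(type,
        DEL = c("left", "right"),
        DUP = c("right", "left"),
        INV = c("left", "left")
      )
      # DELLY-style CT field refines inversion orientation
      ct <- info_get(info, "CT")
      if (!is.na(ct)) {
        ori <- switch(ct,
          "3to5" = c("left", "right"),
          "5to3" = c("right", "left"),
          "3to3" = c("left", "left"),
          "5to5" = c("right", "right"),
          ori
        )
      }
      fp1 <- ci_of(info, "CIPOS", pos)
      fp2 <- ci_of(info, "CIEND", end)
      recs[[length(recs) + 1L]] <- list(
        id = id, chrom1 = chrom, pos1 = pos, ori1 = ori[1], fp1 = fp1,
        chrom2 = chrom, pos2 = end, ori2 = ori[2], fp2 = fp2,
        filt = filt, tc = tc, nc = nc
      )
    } else if (grepl("[][]", alt)) {
      if (id %in% seen_mates) next
      mate_id <- info_get(info, "MATEID")
      if (is.na(mate_id) || !mate_id %in% ids) {
        warning("SV record ", id, " has no mate in ", basename(path),
                "; dropped")
        next
      }
      bnd <- parse_bnd_alt(alt, id)
      j <- match(mate_id, ids)
      mate_bnd <- parse_bnd_alt(fix[j, "ALT"], mate_id)
      seen_mates <- c(seen_mates, mate_id)
      fp1 <- ci_of(info, "CIPOS", pos)
      fp2 <- ci_of(fix[j, "INFO"], "CIPOS", as.integer(fix[j, "POS"]))
      recs[[length(recs) + 1L]] <- list(
        id = id, chrom1 = chrom, pos1 = pos, ori1 = bnd$ori, fp1 = fp1,
        chrom2 = norm_chrom(fix[j, "CHROM"]), pos2 = as.integer(fix[j, "POS"]),
        ori2 = mate_bnd$ori, fp2 = fp2,
        filt = filt, tc = tc, nc = nc
      )
    } else {
      # single breakend or non-SV record: cannot link two genes
      warning("skipping record ", id, " with unsupported ALT '", alt, "'")
    }
  }
  if (!length(recs)) return(empty_svs(dialect))

  df <- do.call(rbind, lapply(recs, function(r) {
    # genome-order the two breakends of intrachromosomal records
    swap <- r$chrom1 == r$chrom2 && r$pos1 > r$pos2
    if (swap) {
      r[c("chrom1", "pos1", "ori1", "fp1", "chrom2", "pos2", "ori2", "fp2")] <-
        r[c("chrom2", "pos2", "ori2", "fp2", "chrom1", "pos1", "ori1", "fp1")]
    }
    data.frame(
      id = r$id, chrom1 = r$chrom1, pos1 = r$pos1, ori1 = r$ori1,
      fp1_start = r$fp1[1], fp1_end = r$fp1[2],
      chrom2 = r$chrom2, pos2 = r$pos2, ori2 = r$ori2,
      fp2_start = r$fp2[1], fp2_end = r$fp2[2],
      tumor_var = r$tc[1], tumor_ref = r$tc[2],
      normal_var = r$nc[1], normal_ref = r$nc[2],
      filter_status = r$filt, stringsAsFactors = FALSE
    )
  }))
  df$caller <- dialect
  df$sv_type <- classify_sv_type(df$chrom1, df$ori1, df$chrom2, df$ori2,
                                 df$pos1, df$pos2)
  df$length <- ifelse(df$sv_type == "CTX", NA_integer_,
                      abs(df$pos2 - df$pos1))
  df$tumor_af <- compute_af(df$tumor_var, df$tumor_ref)
  df$normal_af <- compute_af(df$normal_var, df$normal_ref)
  df$filter_pass <- df$filter_status == "PASS"
  rownames(df) <- NULL
  df[, sv_columns()]
}

sv_columns <- function() {
  c("caller", "id", "chrom1", "pos1", "ori1", "fp1_start", "fp1_end",
    "chrom2", "pos2", "ori2", "fp2_start", "fp2_end", "sv_type", "length",
    "tumor_var", "tumor_ref", "normal_var", "normal_ref",
    "tumor_af", "normal_af", "filter_status", "filter_pass")
}

empty_svs <- function(dialect = "generic") {
  df <- data.frame(
    caller = character(0), id = character(0),
    chrom1 = character(0), pos1 = integer(0), ori1 = character(0),
    fp1_start = integer(0), fp1_end = integer(0),
    chrom2 = character(0), pos2 = integer(0), ori2 = character(0),
    fp2_start = integer(0), fp2_end = integer(0),
    sv_type = character(0), length = integer(0),
    tumor_var = integer(0), tumor_ref = integer(0),
    normal_var = integer(0), normal_ref = integer(0),
    tumor_af = numeric(0), normal_af = numeric(0),
    filter_status = character(0), filter_pass = logical(0),
    stringsAsFactors = FALSE
  )
  df
}

# Inverse of parse_bnd_alt: breakend ALT string from two oriented ends.
# The mate bracket opens toward the side of the mate that is NOT retained.
make_bnd_alt <- function(ori_here, chrom_mate, pos_mate, ori_mate) {
  br <- if (ori_mate == "right") "[" else "]"
  piece <- paste0(br, chrom_mate, ":", pos_mate, br)
  if (ori_here == "left") paste0("N", piece) else paste0(piece, "N")
}

# VCF breakend ALT grammar: t[p[, t]p], [p[t, ]p]t.
# ALT starting with a bracket retains the RIGHT side of this breakend's
# position; ALT starting with sequence retains the LEFT side.
parse_bnd_alt <- function(alt, id) {
  m <- regexec("^([ACGTN]*)([][])([^:]+):([0-9]+)([][])([ACGTN]*)$", alt)
  g <- regmatches(alt, m)[[1]]
  if (!length(g)) stop("unparseable breakend ALT '", alt, "' in record ", id)
  list(
    ori = if (nzchar(g[2])) "left" else "right",
    mate_chrom = sub("^chr", "", g[4]),
    mate_pos = as.integer(g[5])
  )
}

#' Classify an SV type from its two oriented breakends
#'
#' Different chromosomes give an interchromosomal translocation (CTX).
#' On one chromosome the orientations at the genome-ordered breakends
#' decide the type: left-retained at the lower position joined to
#' right-retained at the higher is a deletion; the converse a (tandem)
#' duplication; equal orientations an inversion. The classification is
#' invariant under swapping the two breakends.
#'
#' @param chrom1,chrom2 Chromosomes of the two breakends.
#' @param ori1,ori2 Retained side at each breakend (`"left"`/`"right"`).
#' @param pos1,pos2 Positions (used to genome-order the pair).
#' @return Character vector: `"DEL"`, `"DUP"`, `"INV"` or `"CTX"`.
#' @export
classify_sv_type <- function(chrom1, ori1, chrom2, ori2,
                             pos1 = 0L, pos2 = 1L) {
  n <- max(length(chrom1), length(chrom2))
  chrom1 <- rep_len(chrom1, n); chrom2 <- rep_len(chrom2, n)
  ori1 <- rep_len(ori1, n); ori2 <- rep_len(ori2, n)
  pos1 <- rep_len(pos1, n); pos2 <- rep_len(pos2, n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (chrom1[i] != chrom2[i]) {
      out[i] <- "CTX"
      next
    }
    lo <- if (pos1[i] <= pos2[i]) ori1[i] else ori2[i]
    hi <- if (pos1[i] <= pos2[i]) ori2[i] else ori1[i]
    out[i] <- if (lo == hi) "INV" else if (lo == "left") "DEL" else "DUP"
  }
  out
}

#' Allele fraction from variant and reference read counts
#'
#' @param variant_reads,reference_reads Non-negative read counts
#'   (paired-end plus split-read evidence summed per sample).
#' @return `variant / (variant + reference)`; `NA` at zero total depth
#'   (the record is flagged, not dropped).
#' @export
compute_af <- function(variant_reads, reference_reads) {
  depth <- variant_reads + reference_reads
  ifelse(depth > 0, variant_reads / depth, NA_real_)
}

#' Write normalized SVs as a generic breakend VCF
#'
#' Emits every SV as a `BND` mate pair with `MATEID`, `CIPOS` footprints
#' and a `VR:RR` FORMAT carrying variant/reference read counts for the
#' NORMAL and TUMOR samples, so that
#' `read_sv_vcf(path, dialect = "generic")` round-trips all fields.
#'
#' @param svs data.frame in the layout produced by [read_sv_vcf()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Position confidence interval\">",
    "##FORMAT=<ID=VR,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
    "##FORMAT=<ID=RR,Number=1,Type=Integer,Description=\"Reference-supporting reads\">",
    paste0("##contig=<ID=", unique(c(svs$chrom1, svs$chrom2)), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR"
  )
  lines <- character(0)
  for (i in seq_len(nrow(svs))) {
    r <- svs[i, ]
    ids <- paste0(r$id, c("_1", "_2"))
    ci1 <- sprintf("CIPOS=%d,%d", r$fp1_start - r$pos1, r$fp1_end - r$pos1)
    ci2 <- sprintf("CIPOS=%d,%d", r$fp2_start - r$pos2, r$fp2_end - r$pos2)
    fmt <- "VR:RR"
    nrm <- sprintf("%d:%d", r$normal_var, r$normal_ref)
    tmr <- sprintf("%d:%d", r$tumor_var, r$tumor_ref)
    lines <- c(lines,
      paste(r$chrom1, r$pos1, ids[1], "N",
            make_bnd_alt(r$ori1, r$chrom2, r$pos2, r$ori2), ".",
            r$filter_status,
            paste0("SVTYPE=BND;MATEID=", ids[2], ";", ci1),
            fmt, nrm, tmr, sep = "\t"),
      paste(r$chrom2, r$pos2, ids[2], "N",
            make_bnd_alt(r$ori2, r$chrom1, r$pos1, r$ori1), ".",
            r$filter_status,
            paste0("SVTYPE=BND;MATEID=", ids[1], ";", ci2),
            fmt, nrm, tmr, sep = "\t")
    )
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
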