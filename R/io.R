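## VCF INFO keys understood by the reader/writer, beyond SVTYPE/END/SVLEN.
VCF_INFO_HEADER <- c(
  '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
  '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
  '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of the SV">',
  '##INFO=<ID=RE,Number=1,Type=Integer,Description="Read support">',
  '##INFO=<ID=MAPQ,Number=1,Type=Float,Description="Median mapping quality of supporting reads">',
  '##INFO=<ID=CIPOS,Number=1,Type=Integer,Description="Width of the confidence interval around POS">',
  '##INFO=<ID=CIEND,Number=1,Type=Integer,Description="Width of the confidence interval around END">',
  '##INFO=<ID=PRECISE,Number=0,Type=Flag,Description="Precise structural variant">',
  '##INFO=<ID=DEPTHPVAL,Number=1,Type=Float,Description="P value of the depth-of-coverage test at the breakpoints">',
  '##INFO=<ID=SUPP,Number=1,Type=Integer,Description="Number of supporting pipelines">'
)

info_field <- function(info, key) {
  ## single-valued KEY=... extraction from raw INFO strings
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$)"), info)
}

ci_width <- function(x) {
  ## CIPOS/CIEND may arrive as a single width or as the VCF pair "-a,b"
  out <- rep(NA_real_, length(x))
  has <- !is.na(x)
  two <- has & grepl(",", x)
  one <- has & !two
  out[one] <- suppressWarnings(abs(as.numeric(x[one])))
  if (any(two)) {
    parts <- strsplit(x[two], ",", fixed = TRUE)
    out[two] <- vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (any(is.na(p))) NA_real_ else abs(max(p) - min(p))
    }, numeric(1))
  }
  out
}

svtype_from_alt <- function(alt) {
  ifelse(grepl("^<DEL", alt), "DEL",
  ifelse(grepl("^<INS", alt), "INS",
  ifelse(grepl("^<DUP", alt), "DUP",
  ifelse(grepl("^<INV", alt), "INV",
  ifelse(grepl("\\[|\\]", alt), "BND", NA_character_)))))
}

#' Read an SV call set from a VCF file
#'
#' Parses SV-style VCF records (symbolic ALT alleles or an `SVTYPE` INFO key)
#' into the canonical record model. The 1-based VCF `POS` is converted to a
#' 0-based start; `SVLEN` is stored as an absolute value; caller features
#' (`RE`, `MAPQ`, `CIPOS`, `CIEND`, `PRECISE`, `DEPTHPVAL`) are taken from
#' INFO when present and left missing (`NA`) otherwise — they are never
#' zero-filled. Records lacking both `SVTYPE` and a recognizable symbolic ALT
#' are skipped with a warning giving the skip count.
#'
#' @param path path to a VCF 4.x file.
#' @param source_label pipeline label recorded on every record.
#' @param dataset optional dataset name.
#' @return An `sv_callset`.
#' @export
read_vcf_callset <- function(path, source_label, dataset = NA_character_) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n_meta <- length(vcf@meta) + 1L  # meta lines plus the #CHROM header line
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(callset(empty_records(), label = source_label, dataset = dataset))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop(sprintf("malformed VCF '%s': non-numeric POS at line %d",
                 path, n_meta + bad))
  }
  info <- fix[, "INFO"]
  info[is.na(info)] <- ""
  svtype <- info_field(info, "SVTYPE")
  alt_type <- svtype_from_alt(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]))
  svtype <- ifelse(is.na(svtype), alt_type, svtype)
  keep <- !is.na(svtype)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    warning(sprintf("%d VCF record(s) without SVTYPE or recognizable ALT skipped in '%s'",
                    n_skip, path))
  }
  if (!any(keep)) {
    return(callset(empty_records(), label = source_label, dataset = dataset))
  }
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  info <- info[keep]
  svtype <- svtype[keep]
  svtype[!svtype %in% c("DEL", "INS", "DUP", "INV", "BND")] <- "other"

  end_info <- suppressWarnings(as.integer(info_field(info, "END")))
  svlen <- suppressWarnings(abs(as.numeric(info_field(info, "SVLEN"))))

  start0 <- pos - 1L
  end0 <- ifelse(svtype == "INS", start0 + 1L,
                 ifelse(!is.na(end_info), end_info, start0 + 1L))
  end0 <- pmax(end0, start0 + 1L)
  svlen <- ifelse(is.na(svlen) & svtype %in% c("DEL", "DUP", "INV"),
                  end0 - start0, svlen)

  rec <- data.frame(
    chrom = fix[, "CHROM"],
    start = start0,
    end = as.integer(end0),
    svtype = svtype,
    svcategory = ifelse(svtype == "DEL", "deletion",
                        ifelse(svtype == "INS", "insertion", NA_character_)),
    svlen = svlen,
    RE = suppressWarnings(as.numeric(info_field(info, "RE"))),
    MAPQ = suppressWarnings(as.numeric(info_field(info, "MAPQ"))),
    CIPOS = ci_width(info_field(info, "CIPOS")),
    CIEND = ci_width(info_field(info, "CIEND")),
    PRECISE = ifelse(info_flag(info, "PRECISE"), TRUE,
                     ifelse(info_flag(info, "IMPRECISE"), FALSE, NA)),
    DEPTHPVAL = suppressWarnings(as.numeric(info_field(info, "DEPTHPVAL"))),
    source = source_label,
    stringsAsFactors = FALSE
  )
  callset(rec, label = source_label, dataset = dataset)
}

#' Read a truth set from a BED file
#'
#' BED carries no SV type, so the category is supplied by the caller (truth
#' sets often arrive as one file per category). BED intervals are 0-based
#' half-open and map directly onto the record model. For deletions the SV
#' length is the interval span; for insertions it is taken from a numeric
#' 4th column when present, else the span.
#'
#' @param path path to a BED3/BED4 file.
#' @param svcategory `"deletion"` or `"insertion"`.
#' @param source_label truth-source label.
#' @param dataset optional dataset name.
#' @return An `sv_callset`.
#' @export
read_bed_truthset <- function(path, svcategory = c("deletion", "insertion"),
                              source_label = "truth", dataset = NA_character_) {
  svcategory <- match.arg(svcategory)
  if (!file.exists(path)) stop("no such BED file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(callset(empty_records(), label = source_label, dataset = dataset))
  }
  tab <- read.table(text = lines, sep = "\t", header = FALSE,
                    colClasses = "character", fill = TRUE)
  if (ncol(tab) < 3) stop("BED file '", path, "' has fewer than 3 columns")
  start <- suppressWarnings(as.integer(tab[[2]]))
  end <- suppressWarnings(as.integer(tab[[3]]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("malformed BED '%s': non-numeric coordinates at data line %d", path, bad))
  }
  if (any(end < start)) {
    bad <- which(end < start)[1]
    stop(sprintf("BED '%s': end < start at data line %d", path, bad))
  }
  svlen <- as.numeric(end - start)
  if (svcategory == "insertion" && ncol(tab) >= 4) {
    col4 <- suppressWarnings(as.numeric(tab[[4]]))
    svlen <- ifelse(is.na(col4), svlen, col4)
  }
  rec <- data.frame(
    chrom = tab[[1]],
    start = start,
    end = end,
    svtype = ifelse(svcategory == "deletion", "DEL", "INS"),
    svcategory = svcategory,
    svlen = svlen,
    source = source_label,
    stringsAsFactors = FALSE
  )
  callset(rec, label = source_label, dataset = dataset)
}

fmt_num <- function(x) {
  ifelse(!is.na(x) & x == round(x), format(x, scientific = FALSE, trim = TRUE),
         format(x, scientific = FALSE, trim = TRUE, digits = 10))
}

#' Write a call set to VCF or BED
#'
#' VCF output carries `SVTYPE`, `END`, `SVLEN` and any present caller features
#' in INFO (deletion `SVLEN` is written negative, per convention; readers take
#' the absolute value). BED output is 0-based half-open with the SV length in
#' the 4th column. Reading a written file reproduces the call set
#' record-for-record for every field the format can carry.
#'
#' @param cs an `sv_callset` (normalized).
#' @param path output file path.
#' @param format `"VCF"` or `"BED"`.
#' @return `path`, invisibly.
#' @export
write_callset <- function(cs, path, format = c("VCF", "BED")) {
  format <- match.arg(format)
  stopifnot(inherits(cs, "sv_callset"))
  r <- cs$records
  if (format == "BED") {
    lines <- if (nrow(r) == 0) character(0) else {
      paste(r$chrom, r$start, r$end, fmt_num(r$svlen), sep = "\t")
    }
    writeLines(c("#chrom\tstart\tend\tsvlen", lines), path)
    return(invisible(path))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=svbenchr;label=%s", cs$label),
    VCF_INFO_HEADER,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(r) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  svtype <- ifelse(!is.na(r$svcategory) & r$svcategory == "deletion", "DEL",
            ifelse(!is.na(r$svcategory) & r$svcategory == "insertion", "INS",
                   r$svtype))
  svlen_signed <- ifelse(svtype == "DEL", -r$svlen, r$svlen)
  info <- paste0("SVTYPE=", svtype, ";END=", r$end,
                 ifelse(is.na(r$svlen), "", paste0(";SVLEN=", fmt_num(svlen_signed))))
  add <- function(info, key, val, fmt = fmt_num) {
    ifelse(is.na(val), info, paste0(info, ";", key, "=", fmt(val)))
  }
  info <- add(info, "RE", r$RE)
  info <- add(info, "MAPQ", r$MAPQ)
  info <- add(info, "CIPOS", r$CIPOS)
  info <- add(info, "CIEND", r$CIEND)
  info <- add(info, "DEPTHPVAL", r$DEPTHPVAL)
  info <- ifelse(is.na(r$PRECISE), info,
                 paste0(info, ";", ifelse(r$PRECISE, "PRECISE", "IMPRECISE")))
  lines <- paste(r$chrom, r$start + 1L, paste0("sv", seq_len(nrow(r))),
                 "N", paste0("<", svtype, ">"), ".", "PASS", info, sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}
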