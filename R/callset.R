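#' @importFrom methods is
#' @importFrom stats median rnorm rpois rbeta rbinom rexp rnbinom runif setNames
#' @importFrom utils head read.table write.table
NULL

## Canonical feature order used throughout (feature matrix columns, model input).
FEATURE_KEYS <- c("SVLEN", "DEPTHPVAL", "RE", "MAPQ", "CIEND", "CIPOS", "PRECISE")

## Caller-reported INFO features carried on each record (PRECISE is logical).
RECORD_FEATURES <- c("RE", "MAPQ", "CIPOS", "CIEND", "PRECISE", "DEPTHPVAL")

MAIN_CHROMS <- paste0("chr", c(1:22, "X", "Y"))

#' Construct an empty SV record table
#'
#' Returns a zero-row data.frame with the canonical SV record columns:
#' `chrom`, 0-based half-open `start`/`end`, raw `svtype` (DEL, INS, DUP, INV,
#' BND, other), normalized `svcategory` (deletion/insertion), `svlen`, the
#' caller-reported features (`RE`, `MAPQ`, `CIPOS`, `CIEND`, `PRECISE`,
#' `DEPTHPVAL`; `NA` when a caller does not provide them), and `source`.
#'
#' @return A zero-row data.frame with the canonical record columns.
#' @export
empty_records <- function() {
  data.frame(
    chrom = character(0),
    start = integer(0),
    end = integer(0),
    svtype = character(0),
    svcategory = character(0),
    svlen = numeric(0),
    RE = numeric(0),
    MAPQ = numeric(0),
    CIPOS = numeric(0),
    CIEND = numeric(0),
    PRECISE = logical(0),
    DEPTHPVAL = numeric(0),
    source = character(0),
    stringsAsFactors = FALSE
  )
}

as_records <- function(df) {
  tmpl <- empty_records()
  for (col in names(tmpl)) {
    if (is.null(df[[col]])) {
      fill <- rep(NA, nrow(df))
      mode(fill) <- mode(tmpl[[col]])
      df[[col]] <- fill
    }
  }
  df <- df[, names(tmpl), drop = FALSE]
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$svtype <- as.character(df$svtype)
  df$svcategory <- as.character(df$svcategory)
  df$svlen <- as.numeric(df$svlen)
  df$PRECISE <- as.logical(df$PRECISE)
  df$source <- as.character(df$source)
  rownames(df) <- NULL
  df
}

#' Create an SV call set
#'
#' A call set bundles the SV records from one pipeline (or one truth source)
#' with its label. Records use 0-based half-open coordinates; insertions are
#' represented as a single reference position (`end = start + 1` after
#' normalization) with the inserted length in `svlen`.
#'
#' @param records data.frame of SV records (see [empty_records()] for the
#'   column contract; missing feature columns are added as `NA`).
#' @param label pipeline or truth-source name.
#' @param dataset optional dataset name.
#' @param sorted logical; whether `records` is already sorted by
#'   (chrom, start, end).
#' @return An object of class `sv_callset`.
#' @export
callset <- function(records = empty_records(), label = "callset",
                    dataset = NA_character_, sorted = FALSE) {
  records <- as_records(records)
  if (nrow(records) > 0 && any(is.na(records$source))) {
    records$source[is.na(records$source)] <- label
  }
  obj <- structure(
    list(label = label, dataset = dataset, records = records, sorted = sorted),
    class = "sv_callset"
  )
  validate_callset(obj)
  obj
}

validate_callset <- function(cs) {
  stopifnot(inherits(cs, "sv_callset"))
  r <- cs$records
  if (nrow(r) == 0) return(invisible(cs))
  if (any(is.na(r$chrom)) || any(is.na(r$start)) || any(is.na(r$end))) {
    stop("call set records must have non-missing chrom/start/end")
  }
  if (any(r$end < r$start)) stop("records with end < start are not allowed")
  if (any(!is.na(r$svlen) & r$svlen < 0)) stop("svlen must be non-negative")
  if (isTRUE(cs$sorted)) {
    o <- order(r$chrom, r$start, r$end)
    if (!identical(o, seq_len(nrow(r)))) stop("callset flagged sorted but records are out of order")
  }
  invisible(cs)
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("sv_callset '%s'%s: %d records (%d deletion, %d insertion)%s\n",
              x$label,
              if (is.na(x$dataset)) "" else sprintf(" [%s]", x$dataset),
              nrow(x$records),
              sum(x$records$svcategory == "deletion", na.rm = TRUE),
              sum(x$records$svcategory == "insertion", na.rm = TRUE),
              if (isTRUE(x$sorted)) ", sorted" else ""))
  invisible(x)
}

#' @export
length.sv_callset <- function(x) nrow(x$records)

#' Sort a call set by (chrom, start, end)
#'
#' @param cs an `sv_callset`.
#' @return The call set with records ordered and `sorted = TRUE`.
#' @export
sort_callset <- function(cs) {
  stopifnot(inherits(cs, "sv_callset"))
  r <- cs$records
  r <- r[order(r$chrom, r$start, r$end), , drop = FALSE]
  rownames(r) <- NULL
  cs$records <- r
  cs$sorted <- TRUE
  cs
}

#' Subset a call set to one SV category
#'
#' @param cs an `sv_callset`.
#' @param category `"deletion"` or `"insertion"`.
#' @return A call set containing only records of that category.
#' @export
subset_category <- function(cs, category = c("deletion", "insertion")) {
  category <- match.arg(category)
  cs$records <- cs$records[!is.na(cs$records$svcategory) &
                             cs$records$svcategory == category, , drop = FALSE]
  rownames(cs$records) <- NULL
  cs
}

## GRanges view of a record table. Internal 0-based half-open coordinates map
## to 1-based closed IRanges as [start+1, end]; insertion records become
## width-1 point ranges at the insertion position. `levels` fixes the
## seqlevels so two views are directly comparable without seqlevel warnings.
records_granges <- function(records, levels = unique(records$chrom)) {
  if (nrow(records) == 0 && length(levels) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = factor(records$chrom, levels = levels),
    ranges = IRanges::IRanges(start = records$start + 1L,
                              end = pmax(records$end, records$start + 1L))
  )
}
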