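normalize_chrom_names <- function(chrom) {
  chrom <- ifelse(grepl("^chr", chrom, ignore.case = TRUE),
                  sub("^chr", "chr", chrom, ignore.case = TRUE),
                  paste0("chr", chrom))
  sub("^chrMT$", "chrM", chrom)
}

#' Normalize an SV call set
#'
#' Applies the standard filtering used before any evaluation or integration
#' step: records on unplaced contigs and the mitochondrial genome are dropped
#' (only chr1-chr22, chrX, chrY are kept; names are accepted with or without
#' the "chr" prefix and normalized to the prefixed form); only deletions,
#' insertions and duplications are retained, with duplications relabeled as
#' insertions anchored at the duplication start; insertions are reduced to
#' their point representation (`end = start + 1`); records are filtered for
#' SV size between `min_size` and `max_size` (inclusive); the result is
#' sorted by (chrom, start, end) and same-category records with identical
#' coordinates are collapsed to one. The operation is idempotent.
#'
#' @param cs an `sv_callset` from one of the readers.
#' @param min_size,max_size inclusive SV size bounds in bp.
#' @return A normalized, sorted `sv_callset`.
#' @export
normalize_callset <- function(cs, min_size = 30, max_size = 100000) {
  stopifnot(inherits(cs, "sv_callset"), min_size >= 0, max_size >= min_size)
  r <- cs$records
  if (nrow(r) > 0) {
    r$chrom <- normalize_chrom_names(r$chrom)
    r <- r[r$chrom %in% MAIN_CHROMS, , drop = FALSE]
  }
  if (nrow(r) > 0) {
    ## category assignment: readers set it for DEL/INS; DUP folds into
    ## insertions; INV/BND/other are excluded from evaluation
    cat_missing <- is.na(r$svcategory)
    r$svcategory[cat_missing & r$svtype == "DEL"] <- "deletion"
    r$svcategory[cat_missing & r$svtype %in% c("INS", "DUP")] <- "insertion"
    r <- r[!is.na(r$svcategory) & r$svcategory %in% c("deletion", "insertion"), , drop = FALSE]
  }
  if (nrow(r) > 0) {
    ## size before point-conversion so span-style insertions keep their length
    r$svlen <- ifelse(is.na(r$svlen), as.numeric(r$end - r$start), r$svlen)
    ins <- r$svcategory == "insertion"
    r$end[ins] <- r$start[ins] + 1L
    r <- r[r$svlen >= min_size & r$svlen <= max_size, , drop = FALSE]
  }
  if (nrow(r) > 0) {
    r <- r[order(r$chrom, r$start, r$end, r$svcategory), , drop = FALSE]
    dup <- duplicated(r[, c("chrom", "start", "end", "svcategory")])
    r <- r[!dup, , drop = FALSE]
    rownames(r) <- NULL
  }
  out <- cs
  out$records <- as_records(r)
  out$sorted <- TRUE
  out
}
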