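check_category <- function(cs, category) {
  bad <- cs$records$svcategory[!is.na(cs$records$svcategory)] != category
  if (any(bad)) {
    stop(sprintf("call set '%s' contains records that are not %ss", cs$label, category))
  }
}

new_match_result <- function(calls, truth, call_matched, truth_matched, parameters) {
  cl <- calls$records[, c("chrom", "start", "end", "svcategory", "svlen", "source")]
  cl$label <- ifelse(call_matched, "TP", "FP")
  tl <- truth$records[, c("chrom", "start", "end", "svcategory", "svlen", "source")]
  tl$detected <- truth_matched
  res <- structure(list(
    call_labels = cl,
    truth_labels = tl,
    tp = sum(call_matched),
    fp = sum(!call_matched),
    fn = sum(!truth_matched),
    parameters = parameters
  ), class = "sv_match")
  stopifnot(res$tp + res$fp == nrow(cl), res$fn == nrow(tl) - sum(truth_matched))
  res
}

#' @export
print.sv_match <- function(x, ...) {
  cat(sprintf("sv_match [%s]: TP=%d FP=%d FN=%d\n",
              paste(names(x$parameters), unlist(x$parameters), sep = "=", collapse = ", "),
              x$tp, x$fp, x$fn))
  invisible(x)
}

#' Match a deletion call set against a deletion truth set
#'
#' A call is a true positive if some truth deletion on the same chromosome
#' overlaps it by at least `min_frac` of the call length and, when
#' `reciprocal` is `TRUE` (the default), also at least `min_frac` of the
#' truth length. Truth records are flagged detected under the same criterion.
#' Matching is many-to-many: each record counts once however many partners it
#' has, and no one-to-one assignment is made. The overlap bound is inclusive,
#' so an exactly-50%-reciprocal pair matches at the default threshold.
#'
#' @param calls,truth normalized deletion `sv_callset`s.
#' @param min_frac minimum overlap fraction (of the call; and of the truth
#'   record when `reciprocal`).
#' @param reciprocal require the fraction on both intervals (default) or on
#'   the call only.
#' @return An `sv_match` with per-record labels and TP/FP/FN counts.
#' @export
match_deletions <- function(calls, truth, min_frac = 0.5, reciprocal = TRUE) {
  stopifnot(inherits(calls, "sv_callset"), inherits(truth, "sv_callset"),
            min_frac > 0, min_frac <= 1)
  check_category(calls, "deletion")
  check_category(truth, "deletion")
  nc <- nrow(calls$records); nt <- nrow(truth$records)
  call_matched <- logical(nc); truth_matched <- logical(nt)
  if (nc > 0 && nt > 0) {
    levs <- union(unique(calls$records$chrom), unique(truth$records$chrom))
    gc_ <- records_granges(calls$records, levels = levs)
    gt_ <- records_granges(truth$records, levels = levs)
    hits <- GenomicRanges::findOverlaps(gc_, gt_, ignore.strand = TRUE)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gc_)[qi],
                                               IRanges::ranges(gt_)[si]))
      wc <- calls$records$end[qi] - calls$records$start[qi]
      wt <- truth$records$end[si] - truth$records$start[si]
      ok <- ov >= min_frac * wc
      if (reciprocal) ok <- ok & (ov >= min_frac * wt)
      call_matched[unique(qi[ok])] <- TRUE
      truth_matched[unique(si[ok])] <- TRUE
    }
  }
  new_match_result(calls, truth, call_matched, truth_matched,
                   list(rule = "reciprocal_overlap", min_frac = min_frac,
                        reciprocal = reciprocal))
}

#' Match an insertion call set against an insertion truth set
#'
#' Insertions are represented as single reference positions; a call at
#' position p matches a truth insertion at q on the same chromosome when
#' |p - q| <= `window` (inclusive, so exactly 100 bp apart matches at the
#' default). Matching is symmetric and many-to-many.
#'
#' @param calls,truth normalized insertion `sv_callset`s.
#' @param window maximum breakpoint distance in bp.
#' @return An `sv_match`.
#' @export
match_insertions <- function(calls, truth, window = 100) {
  stopifnot(inherits(calls, "sv_callset"), inherits(truth, "sv_callset"),
            window >= 0)
  check_category(calls, "insertion")
  check_category(truth, "insertion")
  nc <- nrow(calls$records); nt <- nrow(truth$records)
  call_matched <- logical(nc); truth_matched <- logical(nt)
  if (nc > 0 && nt > 0) {
    ## pad call points by the window; a padded call overlaps a truth point
    ## exactly when the positions are within `window` bp
    levs <- union(unique(calls$records$chrom), unique(truth$records$chrom))
    gc_ <- GenomicRanges::GRanges(factor(calls$records$chrom, levels = levs),
                                  IRanges::IRanges(calls$records$start + 1L - window,
                                                   calls$records$start + 1L + window))
    gt_ <- GenomicRanges::GRanges(factor(truth$records$chrom, levels = levs),
                                  IRanges::IRanges(truth$records$start + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(gc_, gt_, ignore.strand = TRUE)
    call_matched[unique(S4Vectors::queryHits(hits))] <- TRUE
    truth_matched[unique(S4Vectors::subjectHits(hits))] <- TRUE
  }
  new_match_result(calls, truth, call_matched, truth_matched,
                   list(rule = "breakpoint_window", window = window))
}

#' Match a call set against truth under its category's rule
#'
#' Dispatches to [match_deletions()] or [match_insertions()].
#'
#' @param calls,truth normalized `sv_callset`s of the given category.
#' @param category `"deletion"` or `"insertion"`.
#' @param min_frac,reciprocal deletion-matching parameters.
#' @param window insertion-matching window in bp.
#' @return An `sv_match`.
#' @export
match_category <- function(calls, truth, category,
                           min_frac = 0.5, reciprocal = TRUE, window = 100) {
  if (category == "deletion") {
    match_deletions(calls, truth, min_frac = min_frac, reciprocal = reciprocal)
  } else {
    match_insertions(calls, truth, window = window)
  }
}

#' Precision, recall and F1 from a match result
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' f1 = 2*precision*recall/(precision+recall). Zero-denominator cases return
#' 0 and set the `degenerate` flag.
#'
#' @param m an `sv_match`, or a list with elements `tp`, `fp`, `fn`.
#' @return An `sv_metrics` object with `precision`, `recall`, `f1`, the
#'   counts, and a `degenerate` flag.
#' @export
compute_metrics <- function(m) {
  tp <- m$tp; fp <- m$fp; fn <- m$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    degenerate <- degenerate || tp == 0
    0
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, degenerate = degenerate),
            class = "sv_metrics")
}

#' @export
print.sv_metrics <- function(x, ...) {
  cat(sprintf("precision=%.4f recall=%.4f F1=%.4f (TP=%d FP=%d FN=%d)%s\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Default SV size bins
#'
#' Six bins covering the normalized size range 30-100,000 bp, chosen to
#' straddle the ~300 bp Alu peak and to separate the sub-200 bp and
#' over-10,000 bp regimes.
#' @return Numeric vector of bin boundaries.
#' @export
default_size_bins <- function() c(30, 100, 200, 500, 1000, 10000, 100000)

size_bin_of <- function(svlen, bins) {
  ## left-closed, right-open; last bin right-closed
  idx <- findInterval(svlen, bins, rightmost.closed = TRUE)
  if (any(idx < 1 | idx >= length(bins))) {
    stop("record svlen outside the stratification bin range")
  }
  idx
}

#' Stratify a match result by SV size
#'
#' Each TP/FP call is assigned to one bin by its call svlen, each missed
#' truth record by its truth svlen (left-closed right-open bins, the last bin
#' right-closed). Per-bin counts sum to the global counts.
#'
#' @param m an `sv_match`.
#' @param bins strictly increasing bin boundaries covering all record sizes.
#' @return A data.frame with one row per bin: bin label, tp, fp, fn,
#'   precision, recall, f1.
#' @export
stratify_by_size <- function(m, bins = default_size_bins()) {
  stopifnot(inherits(m, "sv_match"), length(bins) >= 2, all(diff(bins) > 0))
  nb <- length(bins) - 1
  call_bin <- if (nrow(m$call_labels)) size_bin_of(m$call_labels$svlen, bins) else integer(0)
  truth_bin <- if (nrow(m$truth_labels)) size_bin_of(m$truth_labels$svlen, bins) else integer(0)
  out <- data.frame(
    bin = paste0("[", bins[-length(bins)], ",", bins[-1],
                 c(rep(")", nb - 1), "]")),
    size_min = bins[-length(bins)],
    size_max = bins[-1],
    tp = tabulate(call_bin[m$call_labels$label == "TP"], nb),
    fp = tabulate(call_bin[m$call_labels$label == "FP"], nb),
    fn = tabulate(truth_bin[!m$truth_labels$detected], nb),
    stringsAsFactors = FALSE
  )
  met <- lapply(seq_len(nb), function(i) {
    compute_metrics(list(tp = out$tp[i], fp = out$fp[i], fn = out$fn[i]))
  })
  out$precision <- vapply(met, `[[`, numeric(1), "precision")
  out$recall <- vapply(met, `[[`, numeric(1), "recall")
  out$f1 <- vapply(met, `[[`, numeric(1), "f1")
  out
}

#' Remove calls overlapping repeat regions
#'
#' Drops records overlapping any repeat interval by at least 1 bp (used to
#' exclude simple repeats and low-complexity regions). Insertions are tested
#' on their point position only.
#'
#' @param cs an `sv_callset`.
#' @param repeats repeat regions: a data.frame with `chrom`, `start`, `end`
#'   (0-based half-open, e.g. from a BED file) or a `GRanges`.
#' @return The call set without repeat-overlapping records.
#' @export
filter_repeat_regions <- function(cs, repeats) {
  stopifnot(inherits(cs, "sv_callset"))
  if (is.data.frame(repeats)) {
    repeats <- if (nrow(repeats) == 0) GenomicRanges::GRanges() else
      GenomicRanges::GRanges(repeats$chrom,
                             IRanges::IRanges(repeats$start + 1L, repeats$end))
  }
  if (length(repeats) == 0 || nrow(cs$records) == 0) return(cs)
  levs <- union(unique(cs$records$chrom),
                as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(repeats))))
  GenomeInfoDb::seqlevels(repeats) <- levs
  gr <- records_granges(cs$records, levels = levs)  # insertions are point ranges
  hit <- IRanges::overlapsAny(gr, repeats, ignore.strand = TRUE)
  cs$records <- cs$records[!hit, , drop = FALSE]
  rownames(cs$records) <- NULL
  cs
}

#' Pairwise shared-call counts between call sets
#'
#' Entry (i, j) is the number of records in call set i that are matched by at
#' least one record of call set j under the category's matching rule
#' (reciprocal overlap for deletions, breakpoint window for insertions).
#' The diagonal equals the call-set sizes.
#'
#' @param callsets list of normalized `sv_callset`s of the same category.
#' @param category `"deletion"` or `"insertion"`.
#' @param min_frac,reciprocal,window matching parameters, as in
#'   [match_deletions()] and [match_insertions()].
#' @return An integer matrix with call-set labels on rows and columns.
#' @export
pairwise_overlap_counts <- function(callsets, category = c("deletion", "insertion"),
                                    min_frac = 0.5, reciprocal = TRUE, window = 100) {
  category <- match.arg(category)
  stopifnot(length(callsets) >= 1)
  labels <- vapply(callsets, function(x) x$label, character(1))
  n <- length(callsets)
  out <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m <- match_category(callsets[[i]], callsets[[j]], category,
                          min_frac = min_frac, reciprocal = reciprocal,
                          window = window)
      out[i, j] <- m$tp
    }
  }
  out
}
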