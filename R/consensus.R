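#' Build a consensus call set across pipelines
#'
#' Pools the records of all call sets for one SV category and merges
#' overlapping intervals transitively into clusters (insertion points are
#' padded by `insertion_pad` bp on each side before clustering so positional
#' jitter groups together). Each cluster becomes one consensus call whose
#' interval spans all member intervals and whose support is the number of
#' distinct contributing pipelines (two records from the same pipeline in
#' one cluster count once).
#'
#' @param callsets list of >= 2 normalized `sv_callset`s of the same category.
#' @param category `"deletion"` or `"insertion"`.
#' @param insertion_pad padding in bp applied to insertion points before
#'   clustering; kept equal to the insertion matching window by default.
#' @return A data.frame of class `sv_consensus`: one row per consensus call
#'   with `chrom`, `start`, `end` (envelope of member intervals),
#'   `svcategory`, `svlen` (median of member svlens), `support`, and a
#'   `members` list-column of the contributing records.
#' @export
build_consensus <- function(callsets, category = c("deletion", "insertion"),
                            insertion_pad = 100) {
  category <- match.arg(category)
  if (length(callsets) < 2) stop("consensus requires at least 2 call sets")
  for (cs in callsets) check_category(cs, category)
  pooled <- do.call(rbind, lapply(callsets, function(cs) cs$records))
  pooled <- as_records(pooled)
  n_pipelines <- length(unique(vapply(callsets, function(x) x$label, character(1))))
  if (nrow(pooled) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      svcategory = character(0), svlen = numeric(0),
                      support = integer(0))
    out$members <- list()
    attr(out, "n_pipelines") <- n_pipelines
    class(out) <- c("sv_consensus", "data.frame")
    return(out)
  }
  pad <- if (category == "insertion") as.integer(insertion_pad) else 0L
  gr <- GenomicRanges::GRanges(
    pooled$chrom,
    IRanges::IRanges(pooled$start + 1L - pad, pmax(pooled$end, pooled$start + 1L) + pad)
  )
  ## reduce() yields maximal runs of transitively-overlapping intervals,
  ## i.e. the connected components of the (padded) overlap graph on a line;
  ## min.gapwidth = 0 keeps book-ended (abutting) intervals separate so the
  ## clustering is exactly the transitive closure of >=1 bp overlap
  clusters <- GenomicRanges::reduce(gr, ignore.strand = TRUE, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, clusters, ignore.strand = TRUE)
  stopifnot(length(hits) == nrow(pooled))  # every record in exactly one cluster
  cl_id <- S4Vectors::subjectHits(hits)
  idx <- split(seq_len(nrow(pooled)), cl_id)
  rows <- lapply(idx, function(i) {
    mem <- pooled[i, , drop = FALSE]
    data.frame(chrom = mem$chrom[1],
               start = min(mem$start),
               end = max(mem$end),
               svcategory = category,
               svlen = stats::median(mem$svlen),
               support = length(unique(mem$source)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(idx, function(i) pooled[i, , drop = FALSE])
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pipelines") <- n_pipelines
  class(out) <- c("sv_consensus", "data.frame")
  out
}

#' Filter a consensus set by supporting-pipeline count
#'
#' Keeps consensus calls identified by at least `min_pipelines` distinct
#' pipelines and converts them back to SV records: the merged interval for
#' deletions, the (rounded) median member position for insertions, and the
#' median member svlen in both cases. Results are nested: raising
#' `min_pipelines` can only shrink the set.
#'
#' @param consensus an `sv_consensus` from [build_consensus()].
#' @param min_pipelines minimum number of supporting pipelines (1 to the
#'   number of input pipelines).
#' @param label label for the resulting call set.
#' @return A normalized `sv_callset`.
#' @export
filter_by_support <- function(consensus, min_pipelines, label = NULL) {
  stopifnot(inherits(consensus, "sv_consensus"))
  n_pipelines <- attr(consensus, "n_pipelines")
  if (min_pipelines < 1 || min_pipelines > n_pipelines) {
    stop(sprintf("min_pipelines must be in [1, %d]", n_pipelines))
  }
  if (is.null(label)) label <- sprintf("consensus>=%d", min_pipelines)
  keep <- consensus$support >= min_pipelines
  kept <- consensus[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(callset(empty_records(), label = label))
  }
  category <- kept$svcategory[1]
  start <- if (category == "insertion") {
    vapply(kept$members, function(m) as.integer(round(stats::median(m$start))), integer(1))
  } else {
    kept$start
  }
  end <- if (category == "insertion") start + 1L else kept$end
  rec <- data.frame(chrom = kept$chrom, start = start, end = end,
                    svtype = ifelse(category == "deletion", "DEL", "INS"),
                    svcategory = category, svlen = kept$svlen,
                    source = label, stringsAsFactors = FALSE)
  normalize_callset(callset(rec, label = label))
}

#' Consensus support histogram
#'
#' @param consensus an `sv_consensus`.
#' @return Integer vector: number of consensus calls at each support level
#'   1..n_pipelines.
#' @export
support_histogram <- function(consensus) {
  stopifnot(inherits(consensus, "sv_consensus"))
  n <- attr(consensus, "n_pipelines")
  tabulate(consensus$support, nbins = n)
}

#' F1 as a function of the support threshold
#'
#' Evaluates the support-filtered consensus call set against a truth set for
#' each threshold k, reproducing the consensus F1-vs-support curve.
#'
#' @param consensus an `sv_consensus`.
#' @param truth normalized truth `sv_callset` of the same category.
#' @param ks support thresholds to evaluate (default 1..n_pipelines).
#' @param min_frac,reciprocal,window matching parameters.
#' @return A data.frame with one row per threshold: k, tp, fp, fn,
#'   precision, recall, f1.
#' @export
consensus_f1_curve <- function(consensus, truth, ks = NULL,
                               min_frac = 0.5, reciprocal = TRUE, window = 100) {
  stopifnot(inherits(consensus, "sv_consensus"))
  n <- attr(consensus, "n_pipelines")
  if (is.null(ks)) ks <- seq_len(n)
  category <- if (nrow(consensus) > 0) consensus$svcategory[1] else "deletion"
  rows <- lapply(ks, function(k) {
    cs <- filter_by_support(consensus, k)
    m <- match_category(cs, truth, category, min_frac = min_frac,
                        reciprocal = reciprocal, window = window)
    met <- compute_metrics(m)
    data.frame(k = k, tp = met$tp, fp = met$fp, fn = met$fn,
               precision = met$precision, recall = met$recall, f1 = met$f1)
  })
  do.call(rbind, rows)
}
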