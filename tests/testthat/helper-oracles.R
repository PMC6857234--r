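## Independent brute-force oracles used to cross-check the indexed
## (GenomicRanges-based) implementations. All of them are deliberately
## all-pairs / quadratic and share no code with the package internals.

## All-pairs reciprocal-overlap matching for deletions.
brute_match_deletions <- function(calls, truth, min_frac = 0.5, reciprocal = TRUE) {
  nc <- nrow(calls); nt <- nrow(truth)
  if (nc == 0 || nt == 0) {
    return(list(call = logical(nc), truth = logical(nt)))
  }
  ov <- outer(calls$end, truth$end, pmin) - outer(calls$start, truth$start, pmax)
  same <- outer(calls$chrom, truth$chrom, "==")
  cw <- matrix(calls$end - calls$start, nc, nt)
  tw <- matrix(truth$end - truth$start, nc, nt, byrow = TRUE)
  ok <- same & (ov > 0) & (ov >= min_frac * cw)
  if (reciprocal) ok <- ok & (ov >= min_frac * tw)
  list(call = rowSums(ok) > 0, truth = colSums(ok) > 0)
}

## All-pairs distance matching for insertions (positions = start).
brute_match_insertions <- function(calls, truth, window = 100) {
  nc <- nrow(calls); nt <- nrow(truth)
  if (nc == 0 || nt == 0) {
    return(list(call = logical(nc), truth = logical(nt)))
  }
  d <- abs(outer(calls$start, truth$start, "-"))
  same <- outer(calls$chrom, truth$chrom, "==")
  ok <- same & (d <= window)
  list(call = rowSums(ok) > 0, truth = colSums(ok) > 0)
}

## Union-find transitive clustering of (optionally padded) intervals.
## Returns per-cluster supports (distinct sources) and cluster count.
unionfind_clusters <- function(rec, pad = 0) {
  n <- nrow(rec)
  if (n == 0) return(list(n_clusters = 0, supports = integer(0)))
  s <- rec$start - pad
  e <- pmax(rec$end, rec$start + 1) + pad
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (rec$chrom[i] == rec$chrom[j] && s[i] < e[j] && s[j] < e[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  supports <- vapply(split(rec$source, root),
                     function(x) length(unique(x)), integer(1))
  list(n_clusters = length(unique(root)), supports = unname(sort(supports)))
}

## Right-to-left re-editor: applies recorded SVs to the original reference
## independently of the simulator's left-to-right assembly.
reapply_svs <- function(reference, svs) {
  out <- reference
  for (ch in names(reference)) {
    seq <- reference[[ch]]
    rows <- svs[svs$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$start, decreasing = TRUE), , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      if (rows$svcategory[k] == "deletion") {
        seq <- paste0(substr(seq, 1, rows$start[k]),
                      substr(seq, rows$end[k] + 1, nchar(seq)))
      } else {
        seq <- paste0(substr(seq, 1, rows$start[k]),
                      rows$seq[k],
                      substr(seq, rows$start[k] + 1, nchar(seq)))
      }
    }
    out[[ch]] <- seq
  }
  out
}
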