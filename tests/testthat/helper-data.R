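## Small fixture builders, all programmatic.

del_record <- function(chrom, start, end, source = "p", svlen = end - start) {
  data.frame(chrom = chrom, start = start, end = end, svtype = "DEL",
             svcategory = "deletion", svlen = svlen, source = source,
             stringsAsFactors = FALSE)
}

ins_record <- function(chrom, pos, svlen = 100, source = "p") {
  data.frame(chrom = chrom, start = pos, end = pos + 1, svtype = "INS",
             svcategory = "insertion", svlen = svlen, source = source,
             stringsAsFactors = FALSE)
}

del_callset <- function(starts, ends, chrom = "chr1", label = "calls") {
  callset(del_record(chrom, starts, ends, source = label), label = label)
}

ins_callset <- function(positions, chrom = "chr1", label = "calls", svlen = 100) {
  callset(ins_record(chrom, positions, svlen = svlen, source = label), label = label)
}

## Random non-degenerate interval call set on a toy chromosome.
random_del_callset <- function(n, chrom_len = 1e6, label = "calls",
                               min_w = 30, max_w = 5000) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sapply(w, function(wi) sample.int(chrom_len - wi, 1) - 1L)
  callset(del_record("chr1", s, s + w, source = label), label = label)
}

random_ins_callset <- function(n, chrom_len = 1e6, label = "calls") {
  p <- sample.int(chrom_len - 1, n, replace = TRUE) - 1L
  callset(ins_record("chr1", p, svlen = sample(30:500, n, replace = TRUE),
                     source = label), label = label)
}

random_dna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## A tiny feature-row table with a separable label for classifier tests.
separable_rows <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c(TRUE, FALSE), length.out = n)
    data.frame(
      SVLEN = ifelse(lab, 300, 60) + rnorm(n, 0, 5),
      DEPTHPVAL = -1, RE = -1, MAPQ = -1, CIEND = -1, CIPOS = -1, PRECISE = -1,
      has_SVLEN = 1L, has_DEPTHPVAL = 0L, has_RE = 0L, has_MAPQ = 0L,
      has_CIEND = 0L, has_CIPOS = 0L, has_PRECISE = 0L,
      label = lab
    )
  })
}
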