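#' Subsample reads to a target coverage depth
#'
#' Selects reads uniformly at random without replacement until the
#' cumulative base count first reaches `target_coverage * genome_size`
#' (so the result overshoots the target by less than one read). Used to
#' build reduced-coverage datasets for coverage-titration analyses.
#'
#' @param reads path to a FASTA or FASTQ file, or a
#'   `Biostrings::DNAStringSet`.
#' @param target_coverage desired fold coverage; must not exceed the input
#'   coverage.
#' @param genome_size genome size in bp used to convert bases to coverage.
#' @param seed integer seed.
#' @param out_path optional output path; when given, the subset is written
#'   in the input's format.
#' @return The selected reads as a `DNAStringSet` (quality-scaled if the
#'   input was FASTQ), with attributes `coverage` (achieved fold coverage)
#'   and `n_input`.
#' @export
subsample_reads <- function(reads, target_coverage, genome_size, seed = 1L,
                            out_path = NULL) {
  stopifnot(target_coverage > 0, genome_size > 0)
  fastq <- FALSE
  if (is.character(reads) && length(reads) == 1) {
    fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)
    reads <- if (fastq) {
      Biostrings::readQualityScaledDNAStringSet(reads)
    } else {
      Biostrings::readDNAStringSet(reads)
    }
  }
  stopifnot(methods::is(reads, "DNAStringSet"))
  widths <- Biostrings::width(reads)
  input_cov <- sum(as.numeric(widths)) / genome_size
  if (target_coverage > input_cov + 1e-9) {
    stop(sprintf("target coverage %.2fx exceeds available coverage %.2fx",
                 target_coverage, input_cov))
  }
  ord <- withr::with_seed(seed, sample.int(length(reads)))
  cum <- cumsum(as.numeric(widths[ord]))
  k <- which(cum >= target_coverage * genome_size)[1]
  sel <- sort(ord[seq_len(k)])
  out <- reads[sel]
  attr(out, "coverage") <- sum(as.numeric(widths[sel])) / genome_size
  attr(out, "n_input") <- length(reads)
  if (!is.null(out_path)) {
    if (fastq && methods::is(out, "QualityScaledDNAStringSet")) {
      Biostrings::writeQualityScaledXStringSet(out, out_path)
    } else {
      Biostrings::writeXStringSet(out, out_path)
    }
  }
  out
}
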