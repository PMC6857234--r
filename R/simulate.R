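## deterministic sub-seed derivation (kept within 32-bit integer range)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

random_dna <- function(n) {
  if (n == 0) return("")
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

## Place intervals of the given widths uniformly and without mutual overlap
## on [0, L). Returns 0-based starts. Rejection sampling in rounds; errors
## when the reference cannot accommodate the request.
place_nonoverlapping <- function(widths, L, max_rounds = 200) {
  n <- length(widths)
  if (n == 0) return(integer(0))
  if (any(widths > L)) stop("cannot place SVs: an SV is wider than the reference sequence")
  if (sum(widths) > 0.95 * L) {
    stop("cannot place SVs without overlap: requested SVs span >95% of the reference")
  }
  starts <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    cand <- as.integer(floor(runif(length(remaining)) * (L - widths[remaining] + 1)))
    cand_ir <- IRanges::IRanges(cand + 1L, width = widths[remaining])
    ok <- rep(TRUE, length(remaining))
    placed <- !is.na(starts)
    if (any(placed)) {
      acc_ir <- IRanges::IRanges(starts[placed] + 1L, width = widths[placed])
      ok <- ok & !IRanges::overlapsAny(cand_ir, acc_ir)
    }
    ## resolve collisions among this round's candidates greedily by start
    ord <- order(cand)
    last_end <- -1L
    for (i in ord) {
      if (!ok[i]) next
      s <- cand[i]; e <- s + widths[remaining][i]
      if (s < last_end) ok[i] <- FALSE else last_end <- e
    }
    starts[remaining[ok]] <- cand[ok]
    remaining <- remaining[!ok]
    if (length(remaining) == 0) return(starts)
  }
  stop(sprintf("cannot place %d SV(s) without overlap after %d rounds; reference too dense",
               length(remaining), max_rounds))
}

#' Simulate non-overlapping truth SV intervals
#'
#' Draws deletion and insertion sizes from the size spec and places them
#' uniformly, without mutual overlap, on a genome given as named sequence
#' lengths. Deletions occupy their interval; insertions occupy a single
#' position. SVs are distributed across sequences proportionally to length.
#'
#' @param n_del,n_ins number of deletions and insertions.
#' @param seqlengths named vector of sequence lengths in bp.
#' @param spec size distribution ([size_spec()]).
#' @param seed integer seed.
#' @param label,dataset call-set labels.
#' @return A sorted truth `sv_callset` with a `seqlengths` attribute.
#' @export
simulate_truth_intervals <- function(n_del, n_ins, seqlengths,
                                     spec = size_spec(), seed = 1L,
                                     label = "truth", dataset = "simulated") {
  stopifnot(n_del >= 0, n_ins >= 0, n_del + n_ins > 0,
            length(seqlengths) > 0, !is.null(names(seqlengths)))
  sizes_del <- if (n_del > 0) sample_sv_sizes(n_del, spec, derive_seed(seed, 1)) else integer(0)
  sizes_ins <- if (n_ins > 0) sample_sv_sizes(n_ins, spec, derive_seed(seed, 2)) else integer(0)
  widths <- c(sizes_del, rep(1L, n_ins))
  category <- rep(c("deletion", "insertion"), c(n_del, n_ins))
  svlen <- c(sizes_del, sizes_ins)
  rec <- withr::with_seed(derive_seed(seed, 3), {
    chrom <- names(seqlengths)[
      sample.int(length(seqlengths), length(widths), replace = TRUE,
                 prob = seqlengths / sum(seqlengths))]
    starts <- rep(NA_integer_, length(widths))
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      starts[i] <- place_nonoverlapping(widths[i], seqlengths[[ch]])
    }
    data.frame(
      chrom = chrom,
      start = starts,
      end = starts + widths,
      svtype = ifelse(category == "deletion", "DEL", "INS"),
      svcategory = category,
      svlen = as.numeric(svlen),
      source = label,
      stringsAsFactors = FALSE
    )
  })
  cs <- sort_callset(callset(rec, label = label, dataset = dataset))
  attr(cs, "seqlengths") <- seqlengths
  cs
}

#' Implant SVs into a reference sequence
#'
#' Simulates deletions and insertions in a reference: deletions remove the
#' reference substring at their interval; insertions add random nucleotides
#' at a point (before the base at the insertion position). Placements are
#' uniform among valid non-overlapping positions. Truth coordinates are
#' expressed on the original reference. Defaults mirror a chromosome-20
#' style benchmark design (more insertions than deletions).
#'
#' @param reference named character vector of sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param n_del,n_ins number of deletions and insertions to implant.
#' @param spec size distribution ([size_spec()]).
#' @param seed integer seed.
#' @return An `sv_simtruth`: `svs` (data.frame with `chrom`, `start`, `end`,
#'   `svcategory`, `svlen` and the deleted/inserted sequence `seq`),
#'   `mutated` (named character vector), `seqlengths`, `seed`.
#' @export
implant_svs <- function(reference, n_del = 96, n_ins = 181,
                        spec = size_spec(), seed = 1L) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  seqlengths <- setNames(nchar(reference), names(reference))
  truth <- simulate_truth_intervals(n_del, n_ins, seqlengths, spec = spec,
                                    seed = seed)
  svs <- truth$records[, c("chrom", "start", "end", "svcategory", "svlen")]
  svs$seq <- NA_character_
  mutated <- reference
  withr::with_seed(derive_seed(seed, 4), {
    for (ch in names(reference)) {
      i <- which(svs$chrom == ch)
      if (length(i) == 0) next
      i <- i[order(svs$start[i])]
      refseq <- reference[[ch]]
      parts <- character(0)
      pos <- 0L  # 0-based cursor on the original reference
      for (k in i) {
        parts <- c(parts, substr(refseq, pos + 1L, svs$start[k]))
        if (svs$svcategory[k] == "deletion") {
          svs$seq[k] <- substr(refseq, svs$start[k] + 1L, svs$end[k])
          pos <- svs$end[k]
        } else {
          ins_seq <- random_dna(svs$svlen[k])
          svs$seq[k] <- ins_seq
          parts <- c(parts, ins_seq)
          pos <- svs$start[k]
        }
      }
      parts <- c(parts, substr(refseq, pos + 1L, nchar(refseq)))
      mutated[[ch]] <- paste(parts, collapse = "")
    }
  })
  structure(list(svs = svs, mutated = mutated, seqlengths = seqlengths,
                 seed = as.integer(seed)),
            class = "sv_simtruth")
}

#' @export
print.sv_simtruth <- function(x, ...) {
  cat(sprintf("sv_simtruth: %d deletions + %d insertions on %d sequence(s) (seed %d)\n",
              sum(x$svs$svcategory == "deletion"),
              sum(x$svs$svcategory == "insertion"),
              length(x$seqlengths), x$seed))
  invisible(x)
}

#' Truth call set from an implantation result
#'
#' @param sim an `sv_simtruth`.
#' @param label,dataset call-set labels.
#' @return A sorted truth `sv_callset` (with `seqlengths` attribute).
#' @export
truth_callset <- function(sim, label = "truth", dataset = "simulated") {
  stopifnot(inherits(sim, "sv_simtruth"))
  rec <- sim$svs[, c("chrom", "start", "end", "svcategory", "svlen")]
  rec$svtype <- ifelse(rec$svcategory == "deletion", "DEL", "INS")
  rec$source <- label
  cs <- sort_callset(callset(rec, label = label, dataset = dataset))
  attr(cs, "seqlengths") <- sim$seqlengths
  cs
}

#' Write simulator outputs to a directory
#'
#' Emits the mutated reference as FASTA, the truth set as VCF and as one BED
#' per category, and a YAML provenance record carrying the seed.
#'
#' @param sim an `sv_simtruth`.
#' @param dir output directory (created if missing).
#' @return Named vector of written paths, invisibly.
#' @export
write_simtruth <- function(sim, dir) {
  stopifnot(inherits(sim, "sv_simtruth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "mutated_reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$mutated), fa)
  truth <- truth_callset(sim)
  vcf <- file.path(dir, "truth.vcf")
  write_callset(truth, vcf, "VCF")
  bed_del <- file.path(dir, "truth_deletions.bed")
  write_callset(subset_category(truth, "deletion"), bed_del, "BED")
  bed_ins <- file.path(dir, "truth_insertions.bed")
  write_callset(subset_category(truth, "insertion"), bed_ins, "BED")
  prov <- file.path(dir, "simulation.yaml")
  yaml::write_yaml(list(seed = sim$seed,
                        seqlengths = as.list(sim$seqlengths),
                        n_deletions = sum(sim$svs$svcategory == "deletion"),
                        n_insertions = sum(sim$svs$svcategory == "insertion")),
                   prov)
  invisible(c(fasta = fa, vcf = vcf, bed_deletions = bed_del,
              bed_insertions = bed_ins, provenance = prov))
}
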