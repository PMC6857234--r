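test_that("size sampling respects bounds, the bump limit, and the size profile", {
  ## degenerate bump: everything collapses to ~300 bp
  s <- sample_sv_sizes(500, size_spec(bump_weight = 1, bump_sd = 0), seed = 1)
  expect_true(all(s == 300))
  s2 <- sample_sv_sizes(5000, size_spec(), seed = 2)
  expect_true(all(s2 >= 30 & s2 <= 100000))
  ## default profile: median under 500 bp, modal 100 bp bin containing 300 bp
  s3 <- sample_sv_sizes(10000, size_spec(), seed = 3)
  expect_lt(median(s3), 500)
  breaks <- c(seq(50, 2050, by = 100), 100050)
  counts <- table(cut(s3[s3 >= 50], breaks, right = FALSE))
  expect_equal(as.character(names(which.max(counts))), "[250,350)")
  ## reproducible per seed
  expect_identical(sample_sv_sizes(100, seed = 7), sample_sv_sizes(100, seed = 7))
  expect_error(size_spec(min_size = 0), "bounds")
})

test_that("implantation conserves length and records exact sequences", {
  ref <- setNames(random_dna_seq(10000), "chrA")
  sim <- implant_svs(ref, n_del = 1, n_ins = 0,
                     spec = size_spec(bump_weight = 1, bump_mean = 100, bump_sd = 0),
                     seed = 5)
  expect_equal(nchar(sim$mutated[["chrA"]]), 9900L)
  ## no SVs: identity
  ref2 <- setNames(random_dna_seq(2000), "chrB")
  expect_error(implant_svs(ref2, n_del = 0, n_ins = 0, seed = 1))
  sim0 <- implant_svs(ref2, n_del = 0, n_ins = 1,
                      spec = size_spec(max_size = 100), seed = 1)
  expect_equal(nchar(sim0$mutated[["chrB"]]), 2000L + sim0$svs$svlen[1])
})

test_that("implanted SVs are non-overlapping and reproducible by a re-editor", {
  withr::with_seed(606, {
    for (rep in 1:10) {
      ref <- setNames(random_dna_seq(sample(5000:20000, 1)), "chr1")
      sim <- implant_svs(ref, n_del = sample(1:5, 1), n_ins = sample(1:5, 1),
                         spec = size_spec(max_size = 400),
                         seed = sample.int(1e6, 1))
      svs <- sim$svs
      ## non-overlap on the original reference
      o <- order(svs$start)
      expect_true(all(svs$start[o][-1] >= head(svs$end[o], -1)))
      ## deleted substrings equal the reference at their coordinates
      del <- svs[svs$svcategory == "deletion", ]
      if (nrow(del) > 0) {
        expect_true(all(substr(rep(ref, nrow(del)), del$start + 1, del$end) == del$seq))
      }
      ## length conservation
      expect_equal(nchar(sim$mutated[["chr1"]]),
                   nchar(ref[[1]]) -
                     sum(del$svlen) +
                     sum(svs$svlen[svs$svcategory == "insertion"]))
      ## an independent right-to-left re-editor reproduces the mutated sequence
      expect_identical(reapply_svs(ref, svs)[["chr1"]], sim$mutated[["chr1"]])
    }
  })
})

test_that("a reference too dense to accommodate the SVs errors out", {
  ref <- setNames(random_dna_seq(500), "chr1")
  expect_error(
    implant_svs(ref, n_del = 10, n_ins = 0,
                spec = size_spec(bump_weight = 1, bump_mean = 100, bump_sd = 0),
                seed = 1),
    "cannot place"
  )
})

test_that("noise-free corruption reproduces the truth set exactly", {
  truth <- simulate_truth_intervals(40, 60, c(chr1 = 2e6), seed = 8)
  cfg <- corruption_config(fn_rate = 0, fp_rate = 0)
  cs <- normalize_callset(corrupt_truth_to_callset(truth, cfg, "clean", seed = 1))
  for (category in c("deletion", "insertion")) {
    m <- match_category(subset_category(cs, category),
                        subset_category(truth, category), category)
    met <- compute_metrics(m)
    expect_equal(c(met$precision, met$recall, met$f1), c(1, 1, 1))
  }
  ## fn_rate = 1 silences the call set entirely
  gone <- corrupt_truth_to_callset(truth, corruption_config(fn_rate = 1), "none")
  expect_equal(length(gone), 0L)
})

test_that("corruption recovers the configured error rates", {
  truth <- simulate_truth_intervals(400, 400, c(chr1 = 2e7), seed = 12)
  cfg <- corruption_config(fn_rate = 0.1, fp_rate = 0.25)
  cs <- normalize_callset(corrupt_truth_to_callset(truth, cfg, "noisy", seed = 99))
  counts <- c(tp = 0, fp = 0, fn = 0)
  for (category in c("deletion", "insertion")) {
    m <- match_category(subset_category(cs, category),
                        subset_category(truth, category), category)
    counts <- counts + c(m$tp, m$fp, m$fn)
  }
  met <- compute_metrics(as.list(counts))
  ## centers: recall 0.9; precision 0.9/(0.9+0.25)
  expect_lt(abs(met$recall - 0.9), 3 * sqrt(0.9 * 0.1 / 800))
  expect_lt(abs(met$precision - 0.9 / 1.15), 3.5 * sqrt(0.78 * 0.22 / 920))
})

test_that("pipeline call sets differ by caller and carry the availability pattern", {
  truth <- simulate_truth_intervals(60, 100, c(chr1 = 4e6), seed = 3)
  sets <- simulate_pipeline_callsets(truth, seed = 3)
  expect_equal(length(sets), 7L)
  sniff <- sets[["minimap2-Sniffles"]]$records
  expect_true(all(is.na(sniff$DEPTHPVAL)))
  expect_true(all(!is.na(sniff$RE)))
  nano <- sets[["minimap2-NanoSV"]]$records
  expect_true(all(is.na(nano$RE)))
  expect_true(all(!is.na(nano$DEPTHPVAL)))
  picky <- sets[["LAST-Picky"]]$records
  expect_true(all(is.na(picky$MAPQ)))
  ## the Picky profile is deletion-FP-heavy relative to Sniffles
  expect_gt(sum(picky$svcategory == "deletion"),
            sum(sniff$svcategory == "deletion"))
})

test_that("simulator outputs round-trip through files", {
  ref <- setNames(random_dna_seq(30000), "chr1")
  sim <- implant_svs(ref, n_del = 10, n_ins = 15,
                     spec = size_spec(max_size = 500), seed = 21)
  dir <- tempfile()
  paths <- write_simtruth(sim, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(unname(Biostrings::width(fa)), nchar(sim$mutated[["chr1"]]))
  truth <- truth_callset(sim)
  back <- normalize_callset(read_vcf_callset(paths[["vcf"]], "truth"))
  expect_equal(length(back), length(truth))
  bed <- read_bed_truthset(paths[["bed_deletions"]], "deletion")
  expect_equal(length(bed), 10L)
})

test_that("read subsampling hits the target coverage and stopping rule", {
  withr::with_seed(17, {
    n <- 500
    reads <- Biostrings::DNAStringSet(vapply(
      sample(500:2000, n, replace = TRUE),
      random_dna_seq, character(1)))
    names(reads) <- paste0("read", seq_len(n))
  })
  genome <- 20000
  total_cov <- sum(Biostrings::width(reads)) / genome
  ## full coverage returns every read
  all_back <- subsample_reads(reads, total_cov, genome, seed = 1)
  expect_equal(length(all_back), n)
  sub <- subsample_reads(reads, 10, genome, seed = 1)
  got <- sum(Biostrings::width(sub)) / genome
  expect_gte(got, 10)
  expect_lt(got, 10 + max(Biostrings::width(reads)) / genome)
  ## reproducible per seed, different across seeds, never above input coverage
  expect_identical(names(subsample_reads(reads, 10, genome, seed = 2)),
                   names(subsample_reads(reads, 10, genome, seed = 2)))
  expect_false(identical(names(subsample_reads(reads, 10, genome, seed = 2)),
                         names(sub)))
  expect_error(subsample_reads(reads, total_cov + 5, genome), "exceeds")
  ## file round trip
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(reads, fa)
  sub2 <- subsample_reads(fa, 10, genome, seed = 1,
                          out_path = out <- tempfile(fileext = ".fa"))
  expect_identical(names(sub2), names(sub))
  expect_equal(length(Biostrings::readDNAStringSet(out)), length(sub2))
})
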