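vcf_text <- function(body) {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body)
}

write_tmp <- function(lines, ext = ".vcf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("VCF reader applies the coordinate and sign conventions", {
  path <- write_tmp(vcf_text(c(
    "chr1\t101\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200",
    "chr1\t500\t.\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=-300",
    "chr2\t50\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=80;SVLEN=-30"
  )))
  cs <- read_vcf_callset(path, "test")
  expect_equal(cs$records$start, c(100, 499, 49))
  expect_equal(cs$records$end, c(200, 500, 80))
  expect_equal(cs$records$svlen, c(100, 300, 30))
  expect_equal(cs$records$svcategory, c("deletion", "insertion", "deletion"))
  ## features absent from INFO stay missing, never zero
  expect_true(all(is.na(cs$records$RE)))
  expect_true(all(is.na(cs$records$PRECISE)))
})

test_that("VCF reader flags malformed input and skips typeless records", {
  bad <- write_tmp(vcf_text("chr1\tnotanumber\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=5"))
  expect_error(suppressWarnings(read_vcf_callset(bad, "x")), "line")
  skippy <- write_tmp(vcf_text(c(
    "chr1\t101\t.\tA\tT\t.\tPASS\tFOO=1",
    "chr1\t201\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=300"
  )))
  expect_warning(cs <- read_vcf_callset(skippy, "x"), "skipped")
  expect_equal(length(cs), 1L)
})

test_that("BED truth reader maps intervals and handles degenerate input", {
  path <- write_tmp("chr20\t1000\t1100", ext = ".bed")
  cs <- read_bed_truthset(path, "deletion")
  expect_equal(cs$records[, c("start", "end", "svlen")],
               data.frame(start = 1000L, end = 1100L, svlen = 100))
  ## insertion svlen from the 4th column when present
  path4 <- write_tmp("chr20\t1000\t1001\t350", ext = ".bed")
  ins <- read_bed_truthset(path4, "insertion")
  expect_equal(ins$records$svlen, 350)
  empty <- write_tmp(character(0), ext = ".bed")
  expect_equal(length(read_bed_truthset(empty, "deletion")), 0L)
  bad <- write_tmp("chr1\tabc\t100", ext = ".bed")
  expect_error(read_bed_truthset(bad, "deletion"), "coordinates")
  rev <- write_tmp("chr1\t500\t100", ext = ".bed")
  expect_error(read_bed_truthset(rev, "deletion"), "end < start")
})

test_that("normalization filters, relabels and deduplicates as specified", {
  rec <- rbind(
    del_record("chr1", 0, 29),            # too small
    del_record("chr1", 0, 30),            # exactly min size: kept
    del_record("chr2", 100, 100100),      # 100 kb: kept (inclusive)
    del_record("chr2", 100, 100101),      # > 100 kb: dropped
    del_record("chrM", 10, 100),          # mitochondrial: dropped
    del_record("chrUn_KI270302v1", 10, 100),  # unplaced: dropped
    del_record("3", 500, 700),            # no chr prefix: normalized
    del_record("chr1", 0, 30)             # duplicate of row 2
  )
  dup <- data.frame(chrom = "chr5", start = 1000, end = 1300, svtype = "DUP",
                    svcategory = NA, svlen = NA, source = "p")
  inv <- data.frame(chrom = "chr5", start = 1000, end = 1400, svtype = "INV",
                    svcategory = NA, svlen = NA, source = "p")
  cs <- normalize_callset(callset(rbind(rec, dup, inv), label = "p"))
  r <- cs$records
  expect_equal(nrow(r), 4L)
  expect_true(all(r$chrom %in% paste0("chr", c(1:22, "X", "Y"))))
  expect_true("chr3" %in% r$chrom)
  ## DUP became an insertion point at the DUP start with span svlen
  dup_row <- r[r$chrom == "chr5", ]
  expect_equal(dup_row$svcategory, "insertion")
  expect_equal(dup_row$start, 1000L)
  expect_equal(dup_row$end, 1001L)
  expect_equal(dup_row$svlen, 300)
  expect_false("INV" %in% r$svtype)
})

test_that("normalization is idempotent and enforces record invariants", {
  withr::with_seed(42, {
    cs <- random_del_callset(200)
    ins <- random_ins_callset(100)
    cs$records <- rbind(cs$records, ins$records)
  })
  n1 <- normalize_callset(cs)
  n2 <- normalize_callset(n1)
  expect_identical(n1$records, n2$records)
  r <- n1$records
  expect_true(all(r$start <= r$end))
  expect_true(all(r$svlen >= 30 & r$svlen <= 100000))
  is_ins <- r$svcategory == "insertion"
  expect_true(all(r$end[is_ins] == r$start[is_ins] + 1L))
  expect_false(any(duplicated(r[, c("chrom", "start", "end", "svcategory")])))
})

test_that("VCF writer/reader round-trip is lossless, including features", {
  withr::with_seed(7, {
    n <- 1000
    rec <- rbind(
      del_record("chr1", s <- sort(sample.int(1e6, n / 2)), s + sample(30:5000, n / 2, TRUE),
                 source = "rt"),
      ins_record("chr2", sort(sample.int(1e6, n / 2)),
                 svlen = sample(30:5000, n / 2, TRUE), source = "rt")
    )
    ## random feature availability pattern, including full missingness
    rec$RE <- ifelse(runif(n) < 0.5, sample(0:60, n, TRUE), NA)
    rec$MAPQ <- ifelse(runif(n) < 0.5, sample(0:60, n, TRUE), NA)
    rec$CIPOS <- ifelse(runif(n) < 0.5, sample(0:200, n, TRUE), NA)
    rec$CIEND <- ifelse(runif(n) < 0.5, sample(0:200, n, TRUE), NA)
    rec$PRECISE <- ifelse(runif(n) < 0.3, NA, runif(n) < 0.5)
    rec$DEPTHPVAL <- ifelse(runif(n) < 0.5, round(runif(n), 6), NA)
    cs <- normalize_callset(callset(rec, label = "rt"))
  })
  path <- tempfile(fileext = ".vcf")
  write_callset(cs, path, "VCF")
  back <- normalize_callset(read_vcf_callset(path, "rt"))
  expect_equal(back$records, cs$records)
})

test_that("BED round trip and empty output files are valid", {
  cs <- normalize_callset(del_callset(c(100, 500), c(300, 800), label = "b"))
  path <- tempfile(fileext = ".bed")
  write_callset(cs, path, "BED")
  back <- normalize_callset(read_bed_truthset(path, "deletion", source_label = "b"))
  expect_equal(back$records[, c("chrom", "start", "end", "svlen")],
               cs$records[, c("chrom", "start", "end", "svlen")])
  ## header-only file for an empty set, still readable
  epath <- tempfile(fileext = ".vcf")
  write_callset(callset(label = "e"), epath, "VCF")
  expect_equal(length(read_vcf_callset(epath, "e")), 0L)
})

test_that("a VCF written by the simulator reproduces the truth bookkeeping", {
  ref <- setNames(random_dna_seq(50000), "chr1")
  sim <- implant_svs(ref, n_del = 20, n_ins = 30,
                     spec = size_spec(max_size = 800), seed = 11)
  truth <- truth_callset(sim)
  path <- tempfile(fileext = ".vcf")
  write_callset(truth, path, "VCF")
  back <- read_vcf_callset(path, "truth")
  expect_equal(length(back), 50L)
  expect_equal(back$records[, c("chrom", "start", "end", "svlen")],
               truth$records[, c("chrom", "start", "end", "svlen")])
})
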