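#' Caller feature availability
#'
#' Which of the seven caller-reported features each SV caller provides:
#' Sniffles reports read support and mapping quality but no depth P value or
#' breakpoint confidence intervals; NanoSV reports the depth P value,
#' mapping quality and confidence intervals but no read-support count; Picky
#' reports read support and confidence intervals but no mapping quality.
#' All three report SV length and the PRECISE flag.
#'
#' @param caller `"Sniffles"`, `"NanoSV"` or `"Picky"`, or `"all"` for a
#'   fully available mask.
#' @return Named logical vector over the seven features.
#' @export
caller_feature_availability <- function(caller = c("all", "Sniffles", "NanoSV", "Picky")) {
  caller <- match.arg(caller)
  avail <- setNames(rep(TRUE, length(FEATURE_KEYS)), FEATURE_KEYS)
  if (caller == "Sniffles") avail[c("DEPTHPVAL", "CIEND", "CIPOS")] <- FALSE
  if (caller == "NanoSV") avail["RE"] <- FALSE
  if (caller == "Picky") avail[c("DEPTHPVAL", "MAPQ")] <- FALSE
  avail
}

#' Default caller-style feature model
#'
#' Distributions from which per-call features are drawn, separately for true
#' calls and false calls: read support (negative binomial), median mapping
#' quality (clamped normal on 0-60), depth-of-coverage P value (beta; small
#' for true SVs, near-uniform for false calls), PRECISE flag (Bernoulli) and
#' confidence-interval widths (exponential). True calls get stronger
#' support, higher mapping quality, smaller P values and tighter intervals.
#'
#' @return A list with `tp` and `fp` parameter sets.
#' @export
default_feature_model <- function() {
  list(
    tp = list(RE = c(mu = 26, size = 6),
              MAPQ = c(mean = 52, sd = 6),
              DEPTHPVAL = c(shape1 = 0.4, shape2 = 15),
              PRECISE = 0.85,
              CI = c(mean = 25)),
    fp = list(RE = c(mu = 13, size = 5),
              MAPQ = c(mean = 45, sd = 11),
              DEPTHPVAL = c(shape1 = 1, shape2 = 1),
              PRECISE = 0.35,
              CI = c(mean = 60))
  )
}

draw_features <- function(n, params) {
  if (n == 0) {
    return(data.frame(RE = numeric(0), MAPQ = numeric(0), CIPOS = numeric(0),
                      CIEND = numeric(0), PRECISE = logical(0),
                      DEPTHPVAL = numeric(0)))
  }
  data.frame(
    RE = rnbinom(n, size = params$RE[["size"]], mu = params$RE[["mu"]]),
    MAPQ = pmin(60, pmax(0, round(rnorm(n, params$MAPQ[["mean"]], params$MAPQ[["sd"]])))),
    CIPOS = round(rexp(n, 1 / params$CI[["mean"]])),
    CIEND = round(rexp(n, 1 / params$CI[["mean"]])),
    PRECISE = runif(n) < params$PRECISE,
    DEPTHPVAL = rbeta(n, params$DEPTHPVAL[["shape1"]], params$DEPTHPVAL[["shape2"]])
  )
}

#' Corruption configuration for pipeline-like call sets
#'
#' Controls how a truth set is degraded into a caller-style call set:
#' `fn_rate` is the probability a truth SV is omitted; `fp_rate` is the
#' expected number of false calls per truth SV (the false-call count is
#' Poisson with mean `fp_rate * n_truth`); breakpoints of kept calls are
#' shifted by Gaussian jitter and sizes scaled by a Gaussian factor; features
#' are drawn from the true-call or false-call distributions of the feature
#' model; features the emulated caller does not provide are removed. Rates
#' may be single numbers or named per category
#' (`c(deletion = ..., insertion = ...)`).
#'
#' @param fn_rate fraction of truth SVs omitted (in `[0,1]`).
#' @param fp_rate expected false calls per truth SV (>= 0).
#' @param breakpoint_jitter_sd Gaussian SD of the breakpoint shift, bp.
#' @param size_jitter_sd Gaussian SD of the multiplicative size error.
#' @param features feature model ([default_feature_model()]).
#' @param available feature availability mask
#'   ([caller_feature_availability()]).
#' @param fp_size_spec size spec for false calls; `NULL` draws them from the
#'   same spec as the truth set.
#' @param seed default seed used by [corrupt_truth_to_callset()].
#' @return An `sv_corruption_config`.
#' @export
corruption_config <- function(fn_rate = 0, fp_rate = 0,
                              breakpoint_jitter_sd = 0, size_jitter_sd = 0,
                              features = default_feature_model(),
                              available = caller_feature_availability("all"),
                              fp_size_spec = NULL, seed = 1L) {
  rate_of <- function(x, nm) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- c(deletion = unname(x), insertion = unname(x))
    }
    stopifnot(all(c("deletion", "insertion") %in% names(x)))
    x[c("deletion", "insertion")]
  }
  fn_rate <- rate_of(fn_rate)
  fp_rate <- rate_of(fp_rate)
  stopifnot(all(fn_rate >= 0 & fn_rate <= 1), all(fp_rate >= 0),
            breakpoint_jitter_sd >= 0, size_jitter_sd >= 0)
  structure(list(fn_rate = fn_rate, fp_rate = fp_rate,
                 breakpoint_jitter_sd = breakpoint_jitter_sd,
                 size_jitter_sd = size_jitter_sd,
                 features = features, available = available,
                 fp_size_spec = fp_size_spec, seed = as.integer(seed)),
            class = "sv_corruption_config")
}

## Sample n interval starts for false calls on SV-free positions: uniform
## proposals, rejecting overlap with truth deletions (for deletions) or
## positions within `window` bp of a truth insertion (for insertions).
place_false_calls <- function(n, widths, category, truth_rec, seqlengths,
                              window = 100, max_rounds = 50) {
  if (n == 0) {
    return(data.frame(chrom = character(0), start = integer(0)))
  }
  tr <- truth_rec[truth_rec$svcategory == category, , drop = FALSE]
  avoid <- split(
    if (category == "deletion") {
      IRanges::IRanges(tr$start + 1L, pmax(tr$end, tr$start + 1L))
    } else {
      IRanges::IRanges(tr$start + 1L - window, tr$start + 1L + window)
    },
    tr$chrom
  )
  chrom <- character(n); start <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    m <- length(remaining)
    ch <- names(seqlengths)[sample.int(length(seqlengths), m, replace = TRUE,
                                       prob = seqlengths / sum(seqlengths))]
    w <- widths[remaining]
    limit <- pmax(1, seqlengths[ch] - w + 1)
    s <- as.integer(floor(runif(m) * limit))
    cand <- IRanges::IRanges(s + 1L, width = w)
    ok <- rep(TRUE, m)
    for (cc in unique(ch)) {
      i <- which(ch == cc)
      if (!is.null(avoid[[cc]])) {
        ok[i] <- !IRanges::overlapsAny(cand[i], avoid[[cc]])
      }
    }
    chrom[remaining[ok]] <- ch[ok]
    start[remaining[ok]] <- s[ok]
    remaining <- remaining[!ok]
    if (length(remaining) == 0) break
  }
  keep <- !is.na(start)
  if (any(!keep)) {
    warning(sprintf("dropped %d false call(s) that could not be placed off-truth",
                    sum(!keep)))
  }
  data.frame(chrom = chrom[keep], start = start[keep],
             stringsAsFactors = FALSE)[order(start[keep]), , drop = FALSE]
}

attach_features <- function(rec, is_tp, model, available) {
  feats <- draw_features(nrow(rec), if (is_tp) model$tp else model$fp)
  for (k in RECORD_FEATURES) {
    key <- k
    rec[[key]] <- feats[[key]]
  }
  for (k in names(available)) {
    if (!available[[k]] && k %in% RECORD_FEATURES) rec[[k]] <- NA
  }
  rec
}

#' Corrupt a truth set into a pipeline-like call set
#'
#' Emulates the statistical behavior of an alignment + SV-calling pipeline at
#' the call-set level: each truth SV is kept with probability `1 - fn_rate`;
#' kept calls receive Gaussian breakpoint and size jitter (clamped to valid
#' coordinates and the 30-100,000 bp size range); false calls
#' (Poisson(`fp_rate * n_truth`) per category) are placed uniformly in
#' SV-free regions; caller features are drawn from the true-call or
#' false-call feature model and the caller's availability mask is applied.
#' Optionally, recurrent artifact sites shared across pipelines are included
#' with a per-site probability, emulating systematic caller errors.
#'
#' @param truth an `sv_simtruth` or a truth `sv_callset`.
#' @param cfg an [corruption_config()].
#' @param pipeline_label label for the emitted call set.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @param seqlengths named sequence lengths (taken from `truth` when it
#'   carries them; required for false-call placement otherwise).
#' @param truth_size_spec size spec used for false calls when
#'   `cfg$fp_size_spec` is `NULL`.
#' @param artifact_sites optional data.frame of artifact sites (`chrom`,
#'   `start`, `end`, `svcategory`, `svlen`, `prob`); each is included with
#'   its `prob` and jittered slightly.
#' @return An `sv_callset` (not yet normalized).
#' @export
corrupt_truth_to_callset <- function(truth, cfg, pipeline_label,
                                     seed = NULL, seqlengths = NULL,
                                     truth_size_spec = size_spec(),
                                     artifact_sites = NULL) {
  stopifnot(inherits(cfg, "sv_corruption_config"))
  if (inherits(truth, "sv_simtruth")) {
    seqlengths <- truth$seqlengths
    truth <- truth_callset(truth)
  }
  stopifnot(inherits(truth, "sv_callset"))
  if (is.null(seqlengths)) seqlengths <- attr(truth, "seqlengths")
  if (is.null(seqlengths)) {
    ## fallback: pad the observed extent so clamping and FP placement work
    seqlengths <- tapply(truth$records$end, truth$records$chrom, max) + 10000
  }
  if (is.null(seed)) seed <- cfg$seed
  fp_spec <- if (is.null(cfg$fp_size_spec)) truth_size_spec else cfg$fp_size_spec
  tr <- truth$records
  out <- withr::with_seed(derive_seed(seed, 11), {
    pieces <- list()
    for (category in c("deletion", "insertion")) {
      tcat <- tr[tr$svcategory == category, , drop = FALSE]
      n_truth <- nrow(tcat)
      if (n_truth == 0) next

      ## --- kept true calls, with jitter ---
      keep <- runif(n_truth) < 1 - cfg$fn_rate[[category]]
      kept <- tcat[keep, , drop = FALSE]
      if (nrow(kept) > 0) {
        Lk <- seqlengths[kept$chrom]
        shift <- round(rnorm(nrow(kept), 0, cfg$breakpoint_jitter_sd))
        size_f <- 1 + rnorm(nrow(kept), 0, cfg$size_jitter_sd)
        newlen <- pmin(100000, pmax(30, round(kept$svlen * size_f)))
        start <- pmax(0L, pmin(as.integer(Lk) - 1L, as.integer(kept$start + shift)))
        kept$start <- start
        kept$svlen <- as.numeric(newlen)
        kept$end <- if (category == "deletion") {
          as.integer(pmin(Lk, start + newlen))
        } else {
          start + 1L
        }
        kept <- attach_features(kept, TRUE, cfg$features, cfg$available)
        pieces[[paste0(category, "_tp")]] <- kept
      }

      ## --- false calls ---
      if (cfg$fp_rate[[category]] > 0) {
        n_fp <- rpois(1, cfg$fp_rate[[category]] * n_truth)
        if (n_fp > 0) {
          sizes <- sample_sv_sizes(n_fp, fp_spec,
                                   seed = derive_seed(seed, 13 + match(category, c("deletion", "insertion"))))
          widths <- if (category == "deletion") sizes else rep(1L, n_fp)
          pos <- place_false_calls(n_fp, widths, category, tr, seqlengths)
          if (nrow(pos) > 0) {
            sizes <- sizes[seq_len(nrow(pos))]
            fpr <- data.frame(
              chrom = pos$chrom, start = pos$start,
              end = if (category == "deletion") pos$start + sizes else pos$start + 1L,
              svtype = ifelse(category == "deletion", "DEL", "INS"),
              svcategory = category, svlen = as.numeric(sizes),
              source = pipeline_label, stringsAsFactors = FALSE
            )
            fpr <- attach_features(as_records(fpr), FALSE, cfg$features, cfg$available)
            pieces[[paste0(category, "_fp")]] <- fpr
          }
        }
      }

      ## --- shared artifact sites ---
      if (!is.null(artifact_sites)) {
        art <- artifact_sites[artifact_sites$svcategory == category, , drop = FALSE]
        if (nrow(art) > 0) {
          inc <- runif(nrow(art)) < art$prob
          art <- art[inc, , drop = FALSE]
          if (nrow(art) > 0) {
            La <- seqlengths[art$chrom]
            shift <- round(rnorm(nrow(art), 0, 10))
            start <- pmax(0L, pmin(as.integer(La) - 1L, as.integer(art$start + shift)))
            arr <- data.frame(
              chrom = art$chrom, start = start,
              end = if (category == "deletion") {
                as.integer(pmin(La, start + art$svlen))
              } else start + 1L,
              svtype = ifelse(category == "deletion", "DEL", "INS"),
              svcategory = category, svlen = as.numeric(art$svlen),
              source = pipeline_label, stringsAsFactors = FALSE
            )
            arr <- attach_features(as_records(arr), FALSE, cfg$features, cfg$available)
            pieces[[paste0(category, "_artifact")]] <- arr
          }
        }
      }
    }
    if (length(pieces) == 0) empty_records() else {
      do.call(rbind, lapply(pieces, as_records))
    }
  })
  if (nrow(out) > 0) out$source <- pipeline_label
  sort_callset(callset(out, label = pipeline_label, dataset = truth$dataset))
}
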