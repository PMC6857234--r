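#' Default seven-pipeline noise profiles
#'
#' Shipped corruption profiles for the seven emulated aligner-caller
#' pipelines (three aligners x NanoSV, three aligners x Sniffles, and
#' LAST-Picky). The qualitative structure mirrors what is seen in real
#' long-read benchmarks: NanoSV-style pipelines have high recall but many
#' false calls, Sniffles-style pipelines are precise but miss more events
#' (especially insertions), and the Picky-style pipeline is false-positive
#' heavy for deletions. `fn` and `fp` are per-category miss rates and
#' private (pipeline-specific) false-call rates; correlated false calls
#' shared between pipelines are generated separately from artifact pools
#' ([make_artifact_pools()]).
#'
#' @return Named list of profiles with fields `name`, `aligner`, `caller`,
#'   `fn`, `fp`, `jitter_sd`, `size_jitter_sd`.
#' @export
pipeline_profiles <- function() {
  p <- function(aligner, caller, fn_del, fn_ins, fp_del, fp_ins, jitter_sd) {
    list(name = paste(aligner, caller, sep = "-"), aligner = aligner,
         caller = caller,
         fn = c(deletion = fn_del, insertion = fn_ins),
         fp = c(deletion = fp_del, insertion = fp_ins),
         jitter_sd = jitter_sd, size_jitter_sd = 0.03)
  }
  profiles <- list(
    p("minimap2", "NanoSV",   0.08, 0.10, 0.22, 0.25, 20),
    p("NGMLR",    "NanoSV",   0.10, 0.12, 0.25, 0.28, 20),
    p("GraphMap", "NanoSV",   0.12, 0.14, 0.28, 0.32, 20),
    p("minimap2", "Sniffles", 0.20, 0.25, 0.08, 0.10, 8),
    p("NGMLR",    "Sniffles", 0.25, 0.27, 0.06, 0.08, 8),
    p("GraphMap", "Sniffles", 0.22, 0.24, 0.05, 0.06, 8),
    p("LAST",     "Picky",    0.15, 0.30, 1.00, 0.45, 25)
  )
  setNames(profiles, vapply(profiles, `[[`, character(1), "name"))
}

#' Generate shared artifact-site pools
#'
#' Creates recurrent false-call sites shared across pipelines: a global pool
#' (systematic artifacts any pipeline may report, e.g. at repetitive or
#' low-complexity reference context) and one pool per caller (errors shared
#' by pipelines using the same caller). Pool sites live in SV-free regions
#' and draw their sizes from the false-call size spec. Each site carries a
#' per-caller inclusion probability; a pipeline of caller C includes the
#' site with probability `prob[C]`.
#'
#' Without this correlation structure every false call would be private to
#' one pipeline and support-count filtering would remove false calls almost
#' perfectly at any threshold >= 2; shared artifacts are what give the
#' consensus F1-vs-support curve its interior maximum.
#'
#' @param truth truth `sv_callset`.
#' @param seqlengths named sequence lengths.
#' @param fp_size_spec size spec for artifact sizes.
#' @param seed integer seed.
#' @return A data.frame of sites: `chrom`, `start`, `end`, `svcategory`,
#'   `svlen`, and per-caller probabilities `prob_NanoSV`, `prob_Sniffles`,
#'   `prob_Picky`.
#' @export
make_artifact_pools <- function(truth, seqlengths,
                                fp_size_spec = size_spec(), seed = 1L) {
  tr <- truth$records
  n_del <- sum(tr$svcategory == "deletion")
  n_ins <- sum(tr$svcategory == "insertion")
  pool_def <- list(
    list(category = "deletion", n = round(0.60 * n_del),
         prob = c(NanoSV = 0.55, Sniffles = 0.50, Picky = 0.65)),
    list(category = "deletion", n = round(0.30 * n_del),
         prob = c(NanoSV = 0.60, Sniffles = 0, Picky = 0)),
    list(category = "deletion", n = round(0.12 * n_del),
         prob = c(NanoSV = 0, Sniffles = 0.50, Picky = 0)),
    list(category = "insertion", n = round(0.50 * n_ins),
         prob = c(NanoSV = 0.55, Sniffles = 0.50, Picky = 0.60)),
    list(category = "insertion", n = round(0.15 * n_ins),
         prob = c(NanoSV = 0.50, Sniffles = 0, Picky = 0)),
    list(category = "insertion", n = round(0.08 * n_ins),
         prob = c(NanoSV = 0, Sniffles = 0.50, Picky = 0))
  )
  withr::with_seed(derive_seed(seed, 21), {
    pools <- lapply(seq_along(pool_def), function(i) {
      d <- pool_def[[i]]
      if (d$n == 0) return(NULL)
      sizes <- sample_sv_sizes(d$n, fp_size_spec, seed = derive_seed(seed, 30 + i))
      widths <- if (d$category == "deletion") sizes else rep(1L, d$n)
      pos <- place_false_calls(d$n, widths, d$category, tr, seqlengths)
      if (nrow(pos) == 0) return(NULL)
      sizes <- sizes[seq_len(nrow(pos))]
      data.frame(chrom = pos$chrom, start = pos$start,
                 end = if (d$category == "deletion") pos$start + sizes else pos$start + 1L,
                 svcategory = d$category, svlen = as.numeric(sizes),
                 prob_NanoSV = d$prob[["NanoSV"]],
                 prob_Sniffles = d$prob[["Sniffles"]],
                 prob_Picky = d$prob[["Picky"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pools[!vapply(pools, is.null, logical(1))])
  })
}

#' Simulate the seven pipeline call sets for a truth set
#'
#' Applies the shipped pipeline profiles to a truth set: each pipeline gets
#' its own miss rate, private false calls, breakpoint jitter, a share of the
#' common artifact pools, and its caller's feature availability mask. False
#' calls and artifact sites draw their sizes from `fp_size_spec`, which by
#' default skews smaller than the truth sizes (false calls in long-read data
#' concentrate below ~200 bp) — this is what ties the label signal to SV
#' length for the downstream classifier.
#'
#' @param truth an `sv_simtruth` or truth `sv_callset`.
#' @param seed integer seed.
#' @param profiles pipeline profiles ([pipeline_profiles()]).
#' @param feature_model caller feature model ([default_feature_model()]).
#' @param fp_size_spec size spec for false calls and artifacts.
#' @param seqlengths named sequence lengths (needed when `truth` does not
#'   carry them).
#' @param artifacts include the shared artifact pools? Disable for a
#'   noise-free or uncorrelated-error run.
#' @return Named list of normalized `sv_callset`s, one per pipeline.
#' @export
simulate_pipeline_callsets <- function(truth, seed = 1L,
                                       profiles = pipeline_profiles(),
                                       feature_model = default_feature_model(),
                                       fp_size_spec = size_spec(bump_mean = 70,
                                                                bump_sd = 30,
                                                                bump_weight = 0.75),
                                       seqlengths = NULL, artifacts = TRUE) {
  if (inherits(truth, "sv_simtruth")) {
    seqlengths <- truth$seqlengths
    truth <- truth_callset(truth)
  }
  if (is.null(seqlengths)) seqlengths <- attr(truth, "seqlengths")
  stopifnot(!is.null(seqlengths))
  pools <- if (artifacts) {
    make_artifact_pools(truth, seqlengths, fp_size_spec, seed)
  } else NULL
  out <- lapply(seq_along(profiles), function(i) {
    prof <- profiles[[i]]
    cfg <- corruption_config(
      fn_rate = prof$fn, fp_rate = prof$fp,
      breakpoint_jitter_sd = prof$jitter_sd,
      size_jitter_sd = prof$size_jitter_sd,
      features = feature_model,
      available = caller_feature_availability(prof$caller),
      fp_size_spec = fp_size_spec
    )
    sites <- pools
    if (!is.null(sites)) {
      sites$prob <- sites[[paste0("prob_", prof$caller)]]
    }
    cs <- corrupt_truth_to_callset(truth, cfg, prof$name,
                                   seed = derive_seed(seed, 100 + i),
                                   seqlengths = seqlengths,
                                   artifact_sites = sites)
    normalize_callset(cs)
  })
  setNames(out, names(profiles))
}
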