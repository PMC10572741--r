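# Relative-abundance processing, prevalence filtering, rarefaction and
# alpha diversity for taxon-by-sample count tables.

#' Convert counts to relative abundances
#'
#' @param counts Taxon-by-sample integer matrix.
#' @return Matrix of proportions; each sample column sums to 1.
#' @export
to_relative <- function(counts) {
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    stop_input("to_relative: sample '", colnames(counts)[zero][1],
               "' has zero total")
  }
  sweep(counts, 2, totals, "/")
}

#' Keep taxa reaching a prevalence threshold in at least one sample
#'
#' Mirrors the display rule of showing taxa at >= 2% relative abundance in any
#' sample. Taxa below the threshold everywhere are aggregated into an
#' `other_label` row so columns still sum to 1. The threshold comparison is
#' inclusive (a taxon at exactly the threshold is kept).
#'
#' @param rel Relative-abundance matrix from [to_relative()].
#' @param threshold Prevalence threshold in (0, 1]; default 0.02.
#' @param other_label Row label for the aggregated remainder.
#' @return Filtered relative-abundance matrix (with an `other_label` row when
#'   any taxon was folded).
#' @export
filter_prevalent <- function(rel, threshold = 0.02, other_label = "Other") {
  if (threshold <= 0 || threshold > 1) {
    stop_input("filter_prevalent: threshold must be in (0, 1]")
  }
  keep <- apply(rel, 1, max) >= threshold
  out <- rel[keep, , drop = FALSE]
  if (any(!keep)) {
    other <- colSums(rel[!keep, , drop = FALSE])
    out <- rbind(out, matrix(other, nrow = 1,
                             dimnames = list(other_label, colnames(rel))))
  }
  out
}

#' Rarefy a count table to a fixed depth
#'
#' Draws `depth` reads per sample without replacement (a single seeded draw,
#' mirroring single-depth diversity analyses; use `reps > 1` to average
#' repeated draws and round to the nearest integer for stability checks).
#'
#' @param counts Taxon-by-sample integer matrix.
#' @param depth Target depth; must not exceed any sample total.
#' @param seed Integer RNG seed.
#' @param reps Number of independent draws to average (default 1).
#' @return Rarefied count matrix with every column summing to `depth`
#'   (exactly when `reps = 1`).
#' @export
rarefy <- function(counts, depth, seed, reps = 1) {
  validate_count_table(counts)
  if (depth <= 0) stop_input("rarefy: depth must be > 0")
  totals <- colSums(counts)
  short <- totals < depth
  if (any(short)) {
    stop_input("rarefy: sample '", colnames(counts)[short][1],
               "' has fewer than ", depth, " reads")
  }
  set.seed(derive_seed(seed, "rarefy"))
  draws <- lapply(seq_len(reps), function(i) {
    t(suppressWarnings(vegan::rrarefy(t(counts), depth)))
  })
  if (reps == 1) {
    out <- draws[[1]]
  } else {
    out <- round(Reduce(`+`, draws) / reps)
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}

#' Observed features (richness) per sample
#'
#' @param counts Taxon-by-sample count matrix.
#' @return Named integer vector: number of taxa with nonzero count per sample.
#' @export
observed_features <- function(counts) {
  vegan::specnumber(t(counts))
}

#' Shannon diversity per sample
#'
#' Shannon entropy `H = -sum(p_i * log(p_i))` over nonzero proportions, in
#' base 2 by default (bits), matching the common amplicon-pipeline convention.
#'
#' @param counts Taxon-by-sample count matrix.
#' @param base Logarithm base (default 2).
#' @return Named numeric vector of Shannon indices per sample.
#' @export
shannon_index <- function(counts, base = 2) {
  totals <- colSums(counts)
  if (any(totals <= 0)) stop_input("shannon_index: sample with zero total")
  vegan::diversity(t(counts), index = "shannon", base = base)
}

#' Alpha-diversity summary at a fixed rarefaction depth
#'
#' Rarefies once at `depth` and reports observed features and the Shannon
#' index per sample.
#'
#' @inheritParams rarefy
#' @param base Logarithm base for the Shannon index.
#' @return Data frame with columns `sample_id`, `observed`, `shannon`.
#' @export
alpha_diversity <- function(counts, depth, seed, base = 2) {
  r <- rarefy(counts, depth, seed)
  data.frame(sample_id = colnames(r),
             observed = as.integer(observed_features(r)),
             shannon = as.numeric(shannon_index(r, base = base)),
             stringsAsFactors = FALSE, row.names = NULL)
}
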