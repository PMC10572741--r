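# Functional inference stage: subpathway percentage profiles and day-pair
# ratio selection, taxon-stratified contribution decomposition, and the
# CLR-correlation screen of gene families against dyeing intensity.

#' Subpathway percentage profile per sample
#'
#' Aggregates a function-by-sample abundance table to subpathways via a
#' hierarchy map and expresses each subpathway as a percentage of the
#' sample's total function abundance. Functions without a hierarchy entry are
#' binned as `"Unclassified"`.
#'
#' @param functions Function-by-sample numeric matrix.
#' @param hierarchy Data frame from [read_hierarchy()].
#' @return Subpathway-by-sample matrix of percentages; columns sum to 100.
#' @export
subpathway_percentages <- function(functions, hierarchy) {
  totals <- colSums(functions)
  zero <- totals == 0
  if (any(zero)) {
    stop_input("subpathway_percentages: sample '", colnames(functions)[zero][1],
               "' has zero total abundance")
  }
  sub <- hierarchy$subpathway[match(rownames(functions), hierarchy$function_id)]
  sub[is.na(sub)] <- "Unclassified"
  agg <- rowsum(functions, group = sub)
  sweep(agg, 2, totals, "/") * 100
}

#' Select subpathways by day-pair percentage ratios
#'
#' For each subpathway, computes the ratio of its (replicate-averaged)
#' percentage between pairs of fermentation days — e.g. a high-intensity day
#' over an aged, weakly dyeing day. A subpathway is *selected* when any
#' pair's ratio reaches `select_threshold` (inclusive) and *highlighted* when
#' its mean ratio over `highlight_pairs` exceeds `highlight_threshold`
#' (strict). Subpathways whose denominator percentage is zero in some pair
#' have that ratio undefined; they are reported with `defined = FALSE`,
#' excluded from selection, and counted in a warning rather than fabricated.
#'
#' @param profiles Subpathway-by-sample percentage matrix from
#'   [subpathway_percentages()].
#' @param sample_days Integer vector of fermentation days, one per column of
#'   `profiles` (replicate samples share a day and are averaged first).
#' @param pairs List of `c(numerator_day, denominator_day)` pairs.
#' @param select_threshold Selection threshold on any single ratio
#'   (default 1.05).
#' @param highlight_threshold Highlight threshold on the mean ratio
#'   (default 1.4).
#' @param highlight_pairs Optional subset of `pairs` over which the mean is
#'   taken (default: all pairs).
#' @return Data frame with one row per subpathway: one ratio column per pair
#'   (named e.g. `"D10/D212"`), `mean_ratio`, `defined`, `selected`,
#'   `highlighted`.
#' @export
ratio_select <- function(profiles, sample_days, pairs,
                         select_threshold = 1.05, highlight_threshold = 1.4,
                         highlight_pairs = NULL) {
  if (length(sample_days) != ncol(profiles)) {
    stop_input("ratio_select: sample_days must match the profile columns")
  }
  day_means <- t(rowsum(t(profiles), group = sample_days) /
                   as.vector(table(sample_days)))
  colnames(day_means) <- rownames(rowsum(t(profiles), group = sample_days))
  have <- as.numeric(colnames(day_means))
  pair_name <- function(p) paste0("D", p[1], "/D", p[2])
  ratios <- sapply(pairs, function(p) {
    if (!all(p %in% have)) {
      stop_input("ratio_select: day ", setdiff(p, have)[1],
                 " absent from profiles")
    }
    num <- day_means[, as.character(p[1])]
    den <- day_means[, as.character(p[2])]
    ifelse(den > 0, num / den, NA_real_)
  })
  ratios <- matrix(ratios, nrow = nrow(day_means),
                   dimnames = list(rownames(day_means),
                                   vapply(pairs, pair_name, character(1))))
  if (is.null(highlight_pairs)) highlight_pairs <- pairs
  hcols <- vapply(highlight_pairs, pair_name, character(1))
  defined <- apply(ratios, 1, function(r) all(is.finite(r)))
  if (any(!defined)) {
    warning(sum(!defined), " subpathway(s) with an undefined day-pair ratio ",
            "(zero denominator) excluded from selection", call. = FALSE)
  }
  mean_ratio <- rowMeans(ratios[, hcols, drop = FALSE])
  out <- data.frame(subpathway = rownames(ratios), ratios,
                    mean_ratio = mean_ratio, defined = defined,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$selected <- defined &
    apply(ratios >= select_threshold, 1, any, na.rm = FALSE)
  out$selected[!defined] <- FALSE
  out$highlighted <- defined & !is.na(mean_ratio) &
    mean_ratio > highlight_threshold
  out
}

#' Per-taxon contribution to a set of functions in one sample
#'
#' Sums `CountContributedByOTU` over each taxon's OTUs and the given function
#' set, and expresses every taxon as a percentage of the sample total — the
#' decomposition displayed by taxa-function visualization tools. When a
#' taxon relative-abundance vector is supplied, each taxon's contribution is
#' paired with its abundance for over/under-representation comparison.
#'
#' @param strat Stratified contribution data frame from [read_stratified()]
#'   (must carry a `taxon` column; the `OTU` column is used otherwise).
#' @param function_ids Character vector of function identifiers to aggregate.
#' @param sample_id Sample to decompose.
#' @param taxon_rel Optional named vector of taxon relative abundances in the
#'   sample (proportions or percentages).
#' @return Data frame with columns `taxon`, `contribution_pct`, and
#'   optionally `abundance_pct`, sorted by decreasing contribution.
#' @export
taxon_contribution <- function(strat, function_ids, sample_id,
                               taxon_rel = NULL) {
  if (length(function_ids) == 0) {
    stop_input("taxon_contribution: empty function set")
  }
  rows <- strat[strat$Sample == sample_id & strat$Gene %in% function_ids, ,
                drop = FALSE]
  if (nrow(rows) == 0) {
    stop_input("taxon_contribution: no stratified rows for sample '",
               sample_id, "'")
  }
  taxon <- if ("taxon" %in% names(rows)) rows$taxon else rows$OTU
  by_taxon <- rowsum(rows$CountContributedByOTU, group = taxon)
  total <- sum(by_taxon)
  if (total <= 0) stop_input("taxon_contribution: zero total contribution")
  out <- data.frame(taxon = rownames(by_taxon),
                    contribution_pct = as.numeric(by_taxon) / total * 100,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(taxon_rel)) {
    ab <- taxon_rel[out$taxon]
    if (max(taxon_rel, na.rm = TRUE) <= 1) ab <- ab * 100
    out$abundance_pct <- as.numeric(ab)
  }
  out[order(-out$contribution_pct), , drop = FALSE]
}

#' Per-taxon contribution to a single function in one sample
#'
#' Same arithmetic as [taxon_contribution()] restricted to one function.
#' Returns an empty result (with a warning) when no rows exist for the
#' (function, sample) pair.
#'
#' @inheritParams taxon_contribution
#' @param function_id A single function identifier.
#' @return Data frame as in [taxon_contribution()], possibly empty.
#' @export
otu_contribution_for_function <- function(strat, function_id, sample_id,
                                          taxon_rel = NULL) {
  rows <- strat[strat$Sample == sample_id & strat$Gene == function_id, ,
                drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no stratified rows for function '", function_id,
            "' in sample '", sample_id, "'", call. = FALSE)
    return(data.frame(taxon = character(0), contribution_pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  taxon_contribution(strat, function_id, sample_id, taxon_rel = taxon_rel)
}

#' Centred log-ratio transform of a function abundance table
#'
#' Per sample: zeros are replaced, abundances are closed to proportions,
#' natural logs are taken and the sample's mean log is subtracted, so each
#' sample's transformed values sum to zero. Zero replacement strategies:
#' `"multiplicative"` (default) replaces zeros with half the sample's
#' smallest nonzero proportion and rescales the nonzero part so the
#' composition still sums to one; `"pseudocount"` adds half the smallest
#' nonzero abundance of the sample to every entry.
#'
#' @param functions Function-by-sample numeric matrix (>= 2 functions).
#' @param zero_replacement One of `"multiplicative"`, `"pseudocount"`.
#' @return Matrix of CLR values with the same dimnames.
#' @export
clr_transform <- function(functions,
                          zero_replacement = c("multiplicative", "pseudocount")) {
  zero_replacement <- match.arg(zero_replacement)
  if (nrow(functions) < 2) stop_input("clr_transform: need >= 2 functions")
  if (any(functions < 0)) stop_input("clr_transform: negative abundance")
  if (any(colSums(functions) == 0)) {
    stop_input("clr_transform: sample with all-zero abundances")
  }
  apply(functions, 2, function(x) {
    if (zero_replacement == "pseudocount") {
      if (any(x == 0)) x <- x + min(x[x > 0]) / 2
      p <- x / sum(x)
    } else {
      p <- x / sum(x)
      z <- p == 0
      if (any(z)) {
        delta <- min(p[!z]) / 2
        p[!z] <- p[!z] * (1 - sum(z) * delta)
        p[z] <- delta
      }
    }
    lg <- log(p)
    lg - mean(lg)
  })
}

#' Correlate CLR-transformed functions with a phenotype
#'
#' For each function, the correlation between its CLR values and a per-sample
#' phenotype (dyeing intensity) across samples; functions at or above the
#' selection threshold are flagged. Zero-variance functions have an undefined
#' correlation, are reported as `NA` and are never selected. No
#' multiple-testing correction is applied by default; `adjust = "BH"` adds
#' Benjamini-Hochberg adjusted p-values (from the t-distribution) for users
#' who want them.
#'
#' @param clr_table CLR matrix from [clr_transform()].
#' @param phenotype Numeric phenotype vector; if named, aligned to the CLR
#'   columns by name, otherwise taken in column order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param threshold Selection threshold on the correlation coefficient
#'   (inclusive); 0.9 mirrors a fast-converging (big batch) series, 0.77 a
#'   slow one.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with columns `function_id`, `r`, `selected` (and `p`,
#'   `q` when `adjust = "BH"`), in the input function order.
#' @export
correlate_with_phenotype <- function(clr_table, phenotype,
                                     method = c("pearson", "spearman"),
                                     threshold = 0.9,
                                     adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  n <- ncol(clr_table)
  if (n < 3) stop_input("correlate_with_phenotype: need >= 3 samples")
  if (!is.null(names(phenotype)) && !is.null(colnames(clr_table))) {
    if (!all(colnames(clr_table) %in% names(phenotype))) {
      stop_input("correlate_with_phenotype: phenotype missing for sample '",
                 setdiff(colnames(clr_table), names(phenotype))[1], "'")
    }
    phenotype <- phenotype[colnames(clr_table)]
  }
  if (length(phenotype) != n) {
    stop_input("correlate_with_phenotype: phenotype length must match samples")
  }
  y <- if (method == "spearman") rank(phenotype) else phenotype
  r <- apply(clr_table, 1, function(x) {
    if (method == "spearman") x <- rank(x)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  })
  out <- data.frame(function_id = rownames(clr_table), r = as.numeric(r),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$selected <- !is.na(out$r) & out$r >= threshold
  if (adjust == "BH") {
    tstat <- out$r * sqrt((n - 2) / (1 - out$r^2))
    out$p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    out$q <- stats::p.adjust(out$p, method = "BH")
  }
  out
}
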