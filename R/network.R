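# Spearman rank-correlation co-occurrence networks over genus abundance
# trajectories. Small-sample p-values come from full enumeration of rank
# permutations; longer series use the t-approximation.

#' Genus abundance trajectories from a relative-abundance table
#'
#' Aggregates taxa to genus (sum of proportions) via a taxonomy map and
#' orders sample columns by fermentation day. Replicates are retained as
#' separate, day-ordered trajectory points (more points for rank
#' correlation); set `average_replicates = TRUE` to collapse them.
#'
#' @param rel Taxon-by-sample relative-abundance matrix.
#' @param taxonomy Data frame from [read_taxonomy()]; rows of `rel` absent
#'   from it keep their own label as genus.
#' @param metadata Data frame with `sample_id` and `day` covering the columns
#'   of `rel`.
#' @param drop_labels Row labels to drop before aggregation (default the
#'   `"Other"` bin produced by [filter_prevalent()]).
#' @param average_replicates Collapse same-day replicates to their mean.
#' @return Genus-by-point matrix with a `days` attribute giving each
#'   column's fermentation day.
#' @export
build_trajectories <- function(rel, taxonomy = NULL, metadata,
                               drop_labels = "Other",
                               average_replicates = FALSE) {
  miss <- setdiff(colnames(rel), metadata$sample_id)
  if (length(miss) > 0) {
    stop_input("build_trajectories: sample '", miss[1], "' absent from metadata")
  }
  rel <- rel[!(rownames(rel) %in% drop_labels), , drop = FALSE]
  genus <- rownames(rel)
  if (!is.null(taxonomy)) {
    hit <- match(rownames(rel), taxonomy$otu_id)
    genus[!is.na(hit)] <- taxonomy$genus[hit[!is.na(hit)]]
  }
  m <- rowsum(rel, group = genus)
  days <- metadata$day[match(colnames(m), metadata$sample_id)]
  ord <- order(days, colnames(m))
  m <- m[, ord, drop = FALSE]
  days <- days[ord]
  if (average_replicates) {
    m <- t(rowsum(t(m), group = days) / as.vector(table(days)))
    days <- sort(unique(days))
    colnames(m) <- paste0("day", days)
  }
  if (ncol(m) < 3) stop_input("build_trajectories: need >= 3 sampling points")
  attr(m, "days") <- days
  m
}

#' Spearman rank correlation with a small-sample exact p-value
#'
#' Computes rs as the Pearson correlation of average ranks (correct under
#' ties). The two-sided p-value is exact — full enumeration of the `n!`
#' permutations of one series' ranks — for `n <= exact_n_max`, where the
#' usual t-approximation is poor, and the t-approximation otherwise.
#'
#' @param x,y Numeric series of equal length `n >= 3`.
#' @param exact_n_max Largest `n` for which the permutation null is fully
#'   enumerated (default 8; `8! = 40320` permutations per pair).
#' @return List with elements `rs` and `p` (both `NA` for a zero-variance
#'   series).
#' @export
spearman_edge <- function(x, y, exact_n_max = 8) {
  n <- length(x)
  if (length(y) != n) stop_input("spearman_edge: series lengths differ")
  if (n < 3) stop_input("spearman_edge: need n >= 3")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rs = NA_real_, p = NA_real_))
  }
  rs <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    p <- exact_spearman_p(rx, ry, rs)
  } else {
    tstat <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- min(p, 1)
  }
  list(rs = rs, p = p)
}

# Enumerate all permutations of ry against fixed rx; two-sided p is the
# share of permutations at least as extreme in |rs| (within floating slack).
exact_spearman_p <- function(rx, ry, rs_obs) {
  n <- length(rx)
  P <- all_permutations(n)            # n! x n index matrix
  ry_perm <- matrix(ry[P], nrow = nrow(P))
  rxc <- rx - mean(rx)
  denom <- sqrt(sum(rxc^2))
  ypc <- ry_perm - rowMeans(ry_perm)
  ynorm <- sqrt(rowSums(ypc^2))
  rs_all <- as.numeric(ypc %*% rxc) / (denom * ynorm)
  mean(abs(rs_all) >= abs(rs_obs) - 1e-10)
}

# Iteratively built permutation matrix, cached per n for reuse across pairs.
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- matrix(1L, nrow = 1, ncol = 1)
  if (n > 1) {
    for (k in 2:n) {
      blocks <- lapply(seq_len(k), function(pos) {
        left <- P[, seq_len(pos - 1), drop = FALSE]
        right <- if (pos <= k - 1) P[, pos:(k - 1), drop = FALSE] else NULL
        cbind(left, k, right)
      })
      P <- do.call(rbind, blocks)
    }
  }
  storage.mode(P) <- "integer"
  .perm_cache[[key]] <- P
  P
}

#' Build a co-occurrence network from genus trajectories
#'
#' Retains an undirected edge for every genus pair with `|rs| >
#' rs_threshold` and `p < alpha`; the edge sign is the sign of rs. Node
#' weight is the genus' accumulated relative abundance over the whole
#' period. No multiple-testing correction is applied to edges (`adjust =
#' "BH"` filters on BH-adjusted p instead).
#'
#' @param traj Genus-by-point matrix from [build_trajectories()].
#' @param rs_threshold Strict threshold on `|rs|` (default 0.6).
#' @param alpha Strict threshold on the p-value (default 0.05).
#' @param exact_n_max Passed to [spearman_edge()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `cooccurrence_network`: list with data frames `nodes` (`genus`,
#'   `weight`) and `edges` (`genus_a`, `genus_b`, `rs`, `p`, `sign`).
#' @export
build_network <- function(traj, rs_threshold = 0.6, alpha = 0.05,
                          exact_n_max = 8, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  genera <- rownames(traj)
  nodes <- data.frame(genus = genera, weight = rowSums(traj),
                      stringsAsFactors = FALSE, row.names = NULL)
  pairs <- if (length(genera) >= 2) utils::combn(genera, 2) else
    matrix(character(0), nrow = 2)
  res <- matrix(numeric(0), nrow = 2)
  if (ncol(pairs) > 0) {
    res <- vapply(seq_len(ncol(pairs)), function(j) {
      e <- spearman_edge(traj[pairs[1, j], ], traj[pairs[2, j], ],
                         exact_n_max = exact_n_max)
      c(e$rs, e$p)
    }, numeric(2))
  }
  edges <- data.frame(genus_a = pairs[1, ], genus_b = pairs[2, ],
                      rs = res[1, ], p = res[2, ],
                      stringsAsFactors = FALSE, row.names = NULL)
  edges <- edges[!is.na(edges$rs), , drop = FALSE]
  if (adjust == "BH" && nrow(edges) > 0) {
    edges$p <- stats::p.adjust(edges$p, method = "BH")
  }
  edges <- edges[abs(edges$rs) > rs_threshold & edges$p < alpha, ,
                 drop = FALSE]
  edges$sign <- ifelse(edges$rs > 0, "positive", "negative")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 rs_threshold = rs_threshold, alpha = alpha),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", sum(x$edges$sign == "positive"), " positive, ",
      sum(x$edges$sign == "negative"), " negative; |rs| > ", x$rs_threshold,
      ", p < ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' @param net A `cooccurrence_network` from [build_network()].
#' @return An undirected igraph object with node `weight` and edge `rs`,
#'   `p`, `sign` attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Connected components of a co-occurrence network
#'
#' @param net A `cooccurrence_network`.
#' @return List of `cooccurrence_network` objects, one per connected
#'   component, sorted by node count (descending); isolated genera form
#'   singleton components.
#' @export
network_components <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  ord <- order(-comp$csize)
  lapply(ord, function(ci) {
    members <- names(comp$membership)[comp$membership == ci]
    sub_nodes <- net$nodes[net$nodes$genus %in% members, , drop = FALSE]
    sub_edges <- net$edges[net$edges$genus_a %in% members &
                             net$edges$genus_b %in% members, , drop = FALSE]
    rownames(sub_nodes) <- rownames(sub_edges) <- NULL
    structure(list(nodes = sub_nodes, edges = sub_edges,
                   rs_threshold = net$rs_threshold, alpha = net$alpha),
              class = "cooccurrence_network")
  })
}

#' Write network outputs
#'
#' `write_edge_list()` writes a tab-delimited edge table (`genus_a`,
#' `genus_b`, `rs`, `p`, `sign`) plus a node table (`genus`, `weight`) next
#' to it; `write_graphml()` writes GraphML for network viewers.
#'
#' @param net A `cooccurrence_network`.
#' @param path Output path (for `write_edge_list`, the node table goes to
#'   `<path>.nodes.tsv`).
#' @return Invisibly, `net`.
#' @export
write_edge_list <- function(net, path) {
  edges <- net$edges[order(net$edges$genus_a, net$edges$genus_b), ,
                     drop = FALSE]
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- net$nodes[order(net$nodes$genus), , drop = FALSE]
  utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(net)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(net)
}
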