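# Scan annotated genomes for the flavin-based extracellular electron
# transfer (EET) gene catalogue and classify locus architecture. The
# catalogue covers FAD transport (ecfA, ecfA', fmnA, apbE/fmnB), electron
# transfer (eetA, eetB, ndh2, pplA, frdA-like) and demethylmenaquinone
# synthesis (dmkA, dmkB). Matching works on annotation text only — gene
# names first, product strings second — so the pattern set is shipped as an
# editable data file, not code.

#' Load the EET gene catalogue
#'
#' Tab-delimited with columns `label`, `role_group`, `name_patterns`
#' (`|`-separated gene names, matched case-insensitively and exactly) and
#' `product_patterns` (`|`-separated case-insensitive regular expressions
#' applied to product strings). The default catalogue ships with the
#' package; the ndh2 product patterns deliberately require a type-II/Ndh
#' context so respiratory complex I subunits are not matched.
#'
#' @param path Path to a catalogue file (default: the packaged catalogue).
#' @return Data frame with one row per canonical gene label.
#' @export
eet_catalog <- function(path = system.file("extdata", "eet_catalog.tsv",
                                           package = "indigoferm")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "role_group", "name_patterns", "product_patterns")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_format("catalog '", path, "': missing required column '", miss[1], "'")
  }
  if (anyDuplicated(df$label)) stop_format("catalog '", path, "': duplicated label")
  empty <- !nzchar(df$name_patterns) & !nzchar(df$product_patterns)
  if (any(empty)) {
    stop_format("catalog '", path, "': label '", df$label[empty][1],
                "' has no pattern")
  }
  df
}

#' Match genome features against the EET catalogue
#'
#' A feature matches a label by gene name (case-insensitive exact match
#' against the label's name list) or, failing that, by product regular
#' expression. A feature matching several labels is assigned to the single
#' best one: a name match beats a product match, and among equals the longer
#' (more specific) pattern wins; remaining ties are resolved to the first
#' catalogue label and noted via a message.
#'
#' @param features Feature data frame from [read_gff3()].
#' @param catalog Catalogue data frame from [eet_catalog()].
#' @return Data frame of matches: `label`, `role_group`, `via`
#'   (`"name"`/`"product"`), plus the matched feature's `contig`, `ordinal`,
#'   `start`, `end`, `strand`, `gene`, `product`. Absence of a label is a
#'   result, not an error: labels simply contribute no rows.
#' @export
match_catalog <- function(features, catalog = eet_catalog()) {
  if (nrow(features) == 0) stop_input("match_catalog: empty feature set")
  cand <- list()
  for (i in seq_len(nrow(catalog))) {
    names_i <- tolower(strsplit(catalog$name_patterns[i], "|", fixed = TRUE)[[1]])
    names_i <- names_i[nzchar(names_i)]
    by_name <- !is.na(features$gene) &
      tolower(features$gene) %in% names_i
    # product_patterns is one regular expression (alternation allowed);
    # specificity of a product hit is the length of the matched substring
    pat <- catalog$product_patterns[i]
    by_prod <- rep(FALSE, nrow(features))
    plen <- rep(0L, nrow(features))
    if (nzchar(pat)) {
      has_prod <- !is.na(features$product)
      mm <- regexpr(pat, features$product[has_prod], ignore.case = TRUE,
                    perl = TRUE)
      by_prod[has_prod] <- mm > 0
      plen[has_prod][mm > 0] <- attr(mm, "match.length")[mm > 0]
    }
    hit <- by_name | by_prod
    if (any(hit)) {
      cand[[length(cand) + 1]] <- data.frame(
        feature = which(hit), label = catalog$label[i],
        role_group = catalog$role_group[i],
        via = ifelse(by_name[hit], "name", "product"),
        specificity = ifelse(by_name[hit],
                             1000L + nchar(features$gene[hit]),
                             plen[hit]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) {
    return(cbind(data.frame(label = character(0), role_group = character(0),
                            via = character(0), stringsAsFactors = FALSE),
                 features[integer(0), , drop = FALSE]))
  }
  cand <- do.call(rbind, cand)
  best <- lapply(split(cand, cand$feature), function(d) {
    top <- d[d$specificity == max(d$specificity), , drop = FALSE]
    if (nrow(top) > 1) {
      message("feature at ordinal ", features$ordinal[top$feature[1]],
              " matches several labels (", paste(top$label, collapse = ", "),
              "); keeping '", top$label[1], "'")
    }
    top[1, , drop = FALSE]
  })
  best <- do.call(rbind, best)
  out <- cbind(best[c("label", "role_group", "via")],
               features[best$feature, , drop = FALSE])
  out <- out[order(out$contig, out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster catalogue matches by genomic proximity
#'
#' Single-linkage grouping of matched features on the same contig whose
#' gene-ordinal gap is at most `max_gap_genes` (gene counts rather than base
#' pairs: robust to intergenic length variation). Each role group is then
#' classified: `"clustered"` when all its present labels share one cluster,
#' `"dispersed"` when every matched feature stands alone (all pairwise gaps
#' exceed `max_gap_genes`), `"split"` when the labels spread over two or
#' more clusters at least one of which holds several features, and
#' `"absent"` when nothing matched.
#'
#' @param matches Match data frame from [match_catalog()].
#' @param max_gap_genes Maximum ordinal gap joining two matches (default 10).
#' @param role_groups Role groups to classify (default: those in `matches`,
#'   or supply `catalog$role_group` to also report absent groups).
#' @return List with `matches` (input plus a `cluster` id column) and
#'   `architecture` (data frame `role_group`, `n_labels`, `n_clusters`,
#'   `class`).
#' @export
cluster_matches <- function(matches, max_gap_genes = 10,
                            role_groups = NULL) {
  if (nrow(matches) > 0) {
    ord <- order(matches$contig, matches$ordinal)
    matches <- matches[ord, , drop = FALSE]
    new_cluster <- c(TRUE, diff(matches$ordinal) > max_gap_genes |
                       matches$contig[-1] != matches$contig[-nrow(matches)])
    matches$cluster <- cumsum(new_cluster)
  } else {
    matches$cluster <- integer(0)
  }
  groups <- role_groups %||% unique(matches$role_group)
  architecture <- do.call(rbind, lapply(unique(groups), function(g) {
    rows <- matches[matches$role_group == g, , drop = FALSE]
    cl <- unique(rows$cluster)
    class <- if (nrow(rows) == 0) "absent"
      else if (length(cl) == 1) "clustered"
      else if (length(cl) == nrow(rows)) "dispersed"
      else "split"
    data.frame(role_group = g, n_labels = length(unique(rows$label)),
               n_clusters = length(cl), class = class,
               stringsAsFactors = FALSE)
  }))
  rownames(architecture) <- NULL
  list(matches = matches, architecture = architecture)
}

#' Catalogue completeness of an EET scan
#'
#' @param report An `eet_report` from [eet_scan()].
#' @return List with `fraction` (present labels / catalogue size) and
#'   `role_groups` (data frame with per-group label counts and a `complete`
#'   flag).
#' @export
eet_completeness <- function(report) {
  cat_df <- report$catalog
  present <- unique(report$matches$label)
  by_group <- do.call(rbind, lapply(unique(cat_df$role_group), function(g) {
    labels <- cat_df$label[cat_df$role_group == g]
    data.frame(role_group = g, n_catalog = length(labels),
               n_present = sum(labels %in% present),
               complete = all(labels %in% present),
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  list(fraction = length(intersect(cat_df$label, present)) / nrow(cat_df),
       role_groups = by_group)
}

#' Scan an annotated genome for the EET gene catalogue
#'
#' One-shot wrapper: reads a GFF3 (or takes a feature data frame), matches
#' the catalogue, clusters matches and classifies per-role-group locus
#' architecture.
#'
#' @param gff Path to a GFF3 file, or a feature data frame from
#'   [read_gff3()].
#' @param catalog Catalogue from [eet_catalog()].
#' @param max_gap_genes Passed to [cluster_matches()].
#' @return An `eet_report`: list with `features`, `catalog`, `matches`
#'   (with cluster ids), `architecture`, `presence` (per-label flag) and
#'   `completeness`.
#' @export
eet_scan <- function(gff, catalog = eet_catalog(), max_gap_genes = 10) {
  features <- if (is.character(gff)) read_gff3(gff) else gff
  matches <- match_catalog(features, catalog)
  clustered <- cluster_matches(matches, max_gap_genes = max_gap_genes,
                               role_groups = unique(catalog$role_group))
  presence <- data.frame(label = catalog$label,
                         role_group = catalog$role_group,
                         present = catalog$label %in% clustered$matches$label,
                         stringsAsFactors = FALSE)
  report <- structure(list(features = features, catalog = catalog,
                           matches = clustered$matches,
                           architecture = clustered$architecture,
                           presence = presence),
                      class = "eet_report")
  report$completeness <- eet_completeness(report)
  report
}

#' @export
print.eet_report <- function(x, ...) {
  cat("EET scan: ", sum(x$presence$present), "/", nrow(x$presence),
      " catalogue genes present (completeness ",
      round(x$completeness$fraction, 3), ")\n", sep = "")
  print(x$architecture)
  invisible(x)
}

#' Write an EET scan report as TSV
#'
#' One row per catalogue label: presence, matched location (contig, ordinal
#' span), cluster id and the role group's architecture class, followed by a
#' `# completeness` summary line.
#'
#' @param report An `eet_report`.
#' @param path Output path.
#' @return Invisibly, the per-label table written.
#' @export
write_eet_report <- function(report, path) {
  rows <- lapply(seq_len(nrow(report$presence)), function(i) {
    lab <- report$presence$label[i]
    grp <- report$presence$role_group[i]
    m <- report$matches[report$matches$label == lab, , drop = FALSE]
    arch <- report$architecture$class[report$architecture$role_group == grp]
    data.frame(label = lab, role_group = grp,
               present = nrow(m) > 0,
               contig = if (nrow(m) > 0) paste(unique(m$contig), collapse = ",") else NA,
               ordinal_span = if (nrow(m) > 0)
                 paste(min(m$ordinal), max(m$ordinal), sep = "-") else NA,
               cluster = if (nrow(m) > 0)
                 paste(unique(m$cluster), collapse = ",") else NA,
               architecture = arch, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# completeness\t%.6f\n", report$completeness$fraction),
      file = path, append = TRUE)
  invisible(tab)
}
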