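#' Read a taxon-by-sample count table
#'
#' Count tables are tab-delimited text: the first column holds taxon (OTU/ASV)
#' identifiers, the header row holds sample identifiers, and cells hold
#' non-negative integer read counts.
#'
#' @param path Path to a tab-delimited count table.
#' @return An integer matrix with taxon row names and sample column names.
#' @export
read_count_table <- function(path) {
  m <- read_id_matrix(path, what = "count table")
  bad <- which(!(m >= 0 & m == round(m)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_format("count table '", path, "': negative or non-integer count at row '",
                rownames(m)[bad[1, 1]], "', column '", colnames(m)[bad[1, 2]], "'")
  }
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a taxon-by-sample count table
#'
#' Rows are written in sorted taxon order and columns in sorted sample order so
#' that outputs are diffable.
#'
#' @param table Integer matrix with taxon row names and sample column names.
#' @param path Output path.
#' @return Invisibly, the canonicalized matrix that was written.
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  write_id_matrix(table, path, id_col = "taxon_id")
}

#' Read/write a function-by-sample abundance table
#'
#' Same dialect as [read_count_table()] but rows are gene-family (KEGG
#' ortholog style) identifiers and abundances may be fractional, as produced
#' by metagenome prediction tools.
#'
#' @param path Path to a tab-delimited table.
#' @return A numeric matrix with function row names and sample column names.
#' @export
read_function_table <- function(path) {
  m <- read_id_matrix(path, what = "function table")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stop_format("function table '", path, "': negative abundance at row '",
                rownames(m)[bad[1, 1]], "'")
  }
  m
}

#' @rdname read_function_table
#' @param table Numeric matrix with function row names.
#' @export
write_function_table <- function(table, path) {
  if (any(table < 0)) stop_input("function abundances must be non-negative")
  write_id_matrix(table, path, id_col = "function_id")
}

#' Read/write per-sample metadata
#'
#' Expected columns: `sample_id`, `day`, `batch`, `replicate`, `pH`, `orp_mV`,
#' `dyeing_intensity`. Extra columns are preserved.
#'
#' @param path Path to a tab-delimited metadata table.
#' @return A data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  check_file(path, "metadata")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "day", "batch", "replicate", "pH", "orp_mV",
            "dyeing_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_format("metadata '", path, "': missing required column '", miss[1], "'")
  }
  if (anyDuplicated(df$sample_id)) {
    stop_format("metadata '", path, "': duplicated sample_id '",
                df$sample_id[duplicated(df$sample_id)][1], "'")
  }
  if (any(df$day < 1)) stop_format("metadata '", path, "': day must be >= 1")
  if (any(df$dyeing_intensity < 0)) {
    stop_format("metadata '", path, "': dyeing_intensity must be >= 0")
  }
  df
}

#' @rdname read_sample_metadata
#' @param metadata Data frame with one row per sample.
#' @export
write_sample_metadata <- function(metadata, path) {
  metadata <- metadata[order(metadata$sample_id), , drop = FALSE]
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(metadata)
}

#' Read a stratified (taxon-decomposed) contribution table
#'
#' Reads the legacy per-OTU contribution dialect used by metagenome prediction
#' tools: tab-delimited with columns `Sample`, `Gene`, `OTU`,
#' `GeneCountPerGenome`, `OTUAbundanceInSample`, `CountContributedByOTU`
#' (extra columns preserved). When a taxonomy map is supplied, a `taxon`
#' column with the genus label of each OTU is attached.
#'
#' Rows where `CountContributedByOTU` deviates from the product of the two
#' factor columns by more than `tol` (relative) are kept but flagged with a
#' warning: external files need not satisfy the product identity.
#'
#' @param path Path to a tab-delimited contribution table.
#' @param taxonomy Optional taxonomy data frame from [read_taxonomy()].
#' @param tol Relative tolerance for the product consistency check.
#' @return A data frame of typed contribution rows.
#' @export
read_stratified <- function(path, taxonomy = NULL, tol = 1e-6) {
  check_file(path, "stratified table")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Sample", "Gene", "OTU", "GeneCountPerGenome",
            "OTUAbundanceInSample", "CountContributedByOTU")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_format("stratified table '", path, "': missing required column '",
                miss[1], "'")
  }
  key <- paste(df$Sample, df$Gene, df$OTU, sep = "\r")
  if (anyDuplicated(key)) {
    stop_format("stratified table '", path, "': duplicated (Sample, Gene, OTU) key")
  }
  expected <- df$GeneCountPerGenome * df$OTUAbundanceInSample
  off <- abs(df$CountContributedByOTU - expected) >
    tol * pmax(abs(expected), 1e-300)
  if (any(off)) {
    warning(sum(off), " row(s) in '", path,
            "' have CountContributedByOTU inconsistent with ",
            "GeneCountPerGenome * OTUAbundanceInSample (kept as-is)",
            call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    df$taxon <- taxonomy$genus[match(df$OTU, taxonomy$otu_id)]
    df$taxon[is.na(df$taxon)] <- "Unclassified"
  }
  df
}

#' @rdname read_stratified
#' @param strat Data frame of contribution rows.
#' @export
write_stratified <- function(strat, path) {
  ord <- order(strat$Sample, strat$Gene, strat$OTU)
  strat <- strat[ord, , drop = FALSE]
  utils::write.table(strat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(strat)
}

#' Read a taxonomy map
#'
#' Two tab-delimited columns: OTU identifier and a semicolon-delimited lineage.
#' The genus is the last rank labelled `g__`, or the final lineage token when
#' no rank prefixes are present.
#'
#' @param path Path to the taxonomy file.
#' @return Data frame with columns `otu_id`, `lineage`, `genus`.
#' @export
read_taxonomy <- function(path) {
  check_file(path, "taxonomy")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("otu_id", "lineage"))
  if (anyDuplicated(df$otu_id)) {
    stop_format("taxonomy '", path, "': duplicated otu_id '",
                df$otu_id[duplicated(df$otu_id)][1], "'")
  }
  df$genus <- vapply(df$lineage, genus_from_lineage, character(1),
                     USE.NAMES = FALSE)
  df
}

#' Extract the genus label from a semicolon-delimited lineage
#'
#' @param lineage A lineage string such as
#'   `"d__Bacteria;p__Bacillota;...;g__Alkalibacterium;s__..."`.
#' @return The genus label, or `"Unclassified"` for an empty lineage.
#' @export
genus_from_lineage <- function(lineage) {
  toks <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return("Unclassified")
  g <- toks[startsWith(toks, "g__")]
  if (length(g) > 0) {
    out <- sub("^g__", "", g[length(g)])
    return(if (nzchar(out)) out else "Unclassified")
  }
  sub("^[a-z]__", "", toks[length(toks)])
}

#' Read a function hierarchy map
#'
#' Tab-delimited with columns `function_id`, `subpathway`, `superpathway`,
#' `category`. Screened functions without an entry are binned as
#' `"Unclassified"` by downstream aggregation.
#'
#' @param path Path to the hierarchy file.
#' @return Data frame mapping function identifiers to hierarchy labels.
#' @export
read_hierarchy <- function(path) {
  check_file(path, "hierarchy")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("function_id", "subpathway", "superpathway", "category")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_format("hierarchy '", path, "': missing required column '", miss[1], "'")
  }
  if (anyDuplicated(df$function_id)) {
    stop_format("hierarchy '", path, "': duplicated function_id")
  }
  df
}

#' Read per-pixel CIE L*a*b* measurements
#'
#' Comma-delimited with header columns `L`, `a`, `b`, one row per pixel.
#'
#' @param path Path to the CSV file.
#' @return Data frame with numeric columns `L`, `a`, `b`.
#' @export
read_lab_pixels <- function(path) {
  check_file(path, "pixel table")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("L", "a", "b"), names(df))
  if (length(miss) > 0) {
    stop_format("pixel table '", path, "': missing required column '", miss[1], "'")
  }
  if (nrow(df) == 0) stop_input("pixel table '", path, "' is empty")
  if (any(df$L < 0)) stop_format("pixel table '", path, "': L must be >= 0")
  df[c("L", "a", "b")]
}

#' Read genome annotation features from GFF3
#'
#' Imports CDS features (1-based, end-inclusive coordinates per the GFF3
#' convention) and orders them by contig and start coordinate. Each feature
#' receives an `ordinal` index, consecutive within its contig, used by the
#' gene-cluster scan to measure gene-count distances.
#'
#' @param path Path to a GFF3 file with CDS features carrying `gene` and/or
#'   `product` attributes.
#' @return A data frame with columns `contig`, `start`, `end`, `strand`,
#'   `gene`, `product`, `ordinal`.
#' @export
read_gff3 <- function(path) {
  check_file(path, "GFF3")
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_format("GFF3 '", path, "': ", conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(df) == 0) stop_format("GFF3 '", path, "': no CDS features")
  if (any(df$end < df$start)) {
    stop_format("GFF3 '", path, "': feature with end < start")
  }
  out <- data.frame(
    contig = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    gene = if ("gene" %in% names(df)) as.character(df$gene) else NA_character_,
    product = if ("product" %in% names(df)) as.character(df$product) else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  out$ordinal <- stats::ave(seq_len(nrow(out)), out$contig,
                            FUN = seq_along)
  rownames(out) <- NULL
  out
}

# shared matrix reader/writer ------------------------------------------------

read_id_matrix <- function(path, what) {
  check_file(path, what)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_format(what, " '", path, "': needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop_format(what, " '", path, "': duplicated row identifier '",
                ids[duplicated(ids)][1], "'")
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    stop_format(what, " '", path, "': duplicated sample column '",
                samples[duplicated(samples)][1], "'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_format(what, " '", path, "': non-numeric entries")
  rownames(m) <- ids
  m
}

write_id_matrix <- function(m, path, id_col) {
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

validate_count_table <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_input("count table must carry taxon row names and sample column names")
  }
  if (!is_count(m)) stop_input("count table must hold non-negative integers")
  zero <- colSums(m) == 0
  if (any(zero)) {
    stop_format("count table: sample '", colnames(m)[zero][1],
                "' has no nonzero entry")
  }
  invisible(m)
}
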