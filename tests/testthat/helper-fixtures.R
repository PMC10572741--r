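# Shared fixtures and independent oracles, all built in code at test time.

toy_counts <- function() {
  m <- matrix(c(10L, 30L,
                5L,  5L,
                85L, 65L), nrow = 3, byrow = TRUE,
              dimnames = list(c("otu_a", "otu_b", "otu_c"), c("s1", "s2")))
  m
}

# write a GFF3 file from (contig, start, end, strand, gene, product) rows
write_gff3_fixture <- function(rows, path = tempfile(fileext = ".gff3")) {
  attrs <- vapply(seq_len(nrow(rows)), function(i) {
    a <- sprintf("ID=cds%03d", i)
    if (!is.na(rows$gene[i])) a <- paste0(a, ";gene=", rows$gene[i])
    if (!is.na(rows$product[i])) {
      a <- paste0(a, ";product=", gsub(",", "%2C", rows$product[i]))
    }
    a
  }, character(1))
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                     rows$contig, rows$start, rows$end, rows$strand, attrs))
  writeLines(lines, path)
  path
}

gff_row <- function(contig, start, end, gene = NA, product = NA,
                    strand = "+") {
  data.frame(contig = contig, start = start, end = end, strand = strand,
             gene = gene, product = product, stringsAsFactors = FALSE)
}

# a genome fixture emulating the locus layout reported for the big-batch
# dominant organism: FAD-transport and electron-transfer genes in one
# neighbourhood, DMK genes far away, pplA absent
pelagium_like_gff <- function() {
  filler <- function(contig, ords) {
    do.call(rbind, lapply(ords, function(o) {
      gff_row(contig, o * 1000 + 1, o * 1000 + 900,
              product = "hypothetical protein")
    }))
  }
  rows <- rbind(
    filler("contig1", 1:9),
    gff_row("contig1", 10001, 10900, gene = "ecfA1",
            product = "energy-coupling factor transporter ATP-binding protein EcfA1"),
    gff_row("contig1", 11001, 11900, gene = "ecfA2",
            product = "energy-coupling factor transporter ATP-binding protein EcfA2"),
    gff_row("contig1", 12001, 12900, gene = "fmnA",
            product = "FAD transporter protein"),
    gff_row("contig1", 13001, 13900,
            product = "FAD:protein FMN transferase"),
    filler("contig1", 14:16),
    gff_row("contig1", 17001, 17900, gene = "ndh2",
            product = "type II NADH dehydrogenase"),
    gff_row("contig1", 18001, 18900, gene = "eetB",
            product = "extracellular electron transfer protein EetB"),
    gff_row("contig1", 19001, 19900, gene = "eetA",
            product = "extracellular electron transfer protein EetA"),
    gff_row("contig1", 20001, 20900,
            product = "fumarate reductase flavoprotein subunit"),
    filler("contig1", 21:520),
    gff_row("contig1", 521001, 521900, gene = "dmkA",
            product = "1,4-dihydroxy-2-naphthoate polyprenyltransferase"),
    filler("contig1", 522:560),
    gff_row("contig1", 561001, 561900, gene = "dmkB",
            product = "heptaprenyl diphosphate synthase")
  )
  write_gff3_fixture(rows)
}

# independent Spearman oracle: rs as the rank-Pearson definition written out
# longhand, p by explicit recursive enumeration of all permutations
oracle_spearman <- function(x, y) {
  rs_of <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    num <- sum((ra - mean(ra)) * (rb - mean(rb)))
    den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    num / den
  }
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rs <- rs_of(x, y)
  ry <- rank(y)
  rs_all <- vapply(permute(ry), function(p) rs_of(rank(x), p), numeric(1))
  list(rs = rs, p = mean(abs(rs_all) >= abs(rs) - 1e-10))
}

# brute-force taxon contribution: explicit row-by-row accumulation
oracle_contribution <- function(strat, function_ids, sample_id) {
  acc <- list()
  for (i in seq_len(nrow(strat))) {
    if (strat$Sample[i] == sample_id && strat$Gene[i] %in% function_ids) {
      tx <- strat$taxon[i]
      acc[[tx]] <- (acc[[tx]] %||% 0) + strat$CountContributedByOTU[i]
    }
  }
  v <- unlist(acc)
  100 * v / sum(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_fast_config <- function(seed = 1, ...) {
  synthetic_config("fast_drop", n_functions = 60, n_signal_functions = 8,
                   depth = 4000, seed = seed, ...)
}
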