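# Seeded synthetic fermentation datasets. The generator emulates the
# abundance/function/phenotype structure of a sukumo indigo vat sampled over
# time in two designs: a big batch whose ORP collapses below -600 mV before
# the first sampling day (fast_drop) and a small batch whose ORP only
# reaches the indigo-reducing range around day 5 (slow_drop). Guild latent
# dynamics are logistic; sampling is Dirichlet-multinomial at fixed depth;
# dyeing intensity is a saturating (Hill-type) function of the
# reducer-guild fraction gated by low ORP.

#' Define a taxon guild
#'
#' A guild is a set of taxa sharing one latent trajectory: `decliner`
#' (logistic decay from `baseline_fraction` toward `asymptote`),
#' `early_riser`/`late_riser` (logistic rise from `baseline_fraction` toward
#' `asymptote`) or `stable` (constant at `baseline_fraction`). Members split
#' the guild's latent fraction according to `member_weights`.
#'
#' @param name Guild label.
#' @param members Character vector of taxon (OTU) labels.
#' @param genera Genus label per member (recycled if length 1).
#' @param trajectory_kind One of `"decliner"`, `"early_riser"`,
#'   `"late_riser"`, `"stable"`.
#' @param growth_rate Logistic rate per day (finite).
#' @param midpoint_day Day of half-maximal change (>= 0).
#' @param baseline_fraction Initial compositional fraction in `[0, 1]`.
#' @param asymptote Limiting fraction approached by the logistic.
#' @param member_weights Within-guild fraction split (defaults to equal).
#' @param reducer Whether the guild contributes to indigo reduction.
#' @return A `guild_spec` list.
#' @export
guild_spec <- function(name, members, genera, trajectory_kind,
                       growth_rate = 0.5, midpoint_day = 10,
                       baseline_fraction = 0.1,
                       asymptote = if (trajectory_kind == "decliner") 0 else
                         baseline_fraction,
                       member_weights = NULL, reducer = FALSE) {
  trajectory_kind <- match.arg(trajectory_kind,
                               c("decliner", "early_riser", "late_riser",
                                 "stable"))
  if (!is.finite(growth_rate) && trajectory_kind != "stable") {
    # infinity is accepted as the step limit of the logistic
    growth_rate <- Inf
  }
  if (midpoint_day < 0) stop_invariant("guild_spec: midpoint_day must be >= 0")
  if (baseline_fraction < 0 || baseline_fraction > 1) {
    stop_invariant("guild_spec: baseline_fraction must be in [0, 1]")
  }
  genera <- rep_len(genera, length(members))
  member_weights <- member_weights %||% rep(1 / length(members),
                                            length(members))
  if (length(member_weights) != length(members)) {
    stop_input("guild_spec: member_weights must match members")
  }
  member_weights <- member_weights / sum(member_weights)
  structure(list(name = name, members = members, genera = genera,
                 trajectory_kind = trajectory_kind,
                 growth_rate = growth_rate, midpoint_day = midpoint_day,
                 baseline_fraction = baseline_fraction,
                 asymptote = asymptote, member_weights = member_weights,
                 reducer = reducer),
            class = "guild_spec")
}

#' Latent guild fraction over sampling days
#'
#' Risers follow `baseline + (asymptote - baseline) / (1 + exp(-rate (t -
#' midpoint)))`; decliners follow `asymptote + (baseline - asymptote) / (1 +
#' exp(rate (t - midpoint)))`; stable guilds stay at the baseline. In the
#' infinite-rate limit these become step functions at the midpoint day.
#'
#' @param spec A [guild_spec()].
#' @param days Strictly increasing, nonempty vector of sampling days.
#' @return Numeric vector of latent fractions in `[0, 1]`, one per day.
#' @export
guild_trajectory <- function(spec, days) {
  if (length(days) == 0) stop_input("guild_trajectory: empty day list")
  if (any(diff(days) <= 0)) {
    stop_input("guild_trajectory: days must be strictly increasing")
  }
  x <- spec$growth_rate * (days - spec$midpoint_day)
  logistic <- function(z) {
    out <- 1 / (1 + exp(-z))
    out[z == Inf] <- 1       # step limit
    out[z == -Inf] <- 0
    out[is.nan(z)] <- 0.5    # rate = Inf exactly at the midpoint
    out
  }
  f <- switch(spec$trajectory_kind,
    stable = rep(spec$baseline_fraction, length(days)),
    decliner = spec$asymptote +
      (spec$baseline_fraction - spec$asymptote) * (1 - logistic(x)),
    early_riser = ,
    late_riser = spec$baseline_fraction +
      (spec$asymptote - spec$baseline_fraction) * logistic(x)
  )
  pmin(pmax(f, 0), 1)
}

#' Default guild sets for the two fermentation designs
#'
#' `fast_drop` encodes a big batch that has already converged to the
#' indigo-reducing state at the first sampling: reducer guilds
#' (*Alkalibacterium*, lactic acid bacteria, obligate anaerobes) rise at the
#' expense of a declining pool of many rare background taxa, and
#' *Actinomycetota* are excluded before the first sample. `slow_drop`
#' encodes a small batch in which aerobes (*Bacillus*, *Actinomycetota*)
#' dominate the first sample and are displaced by reducers only once the ORP
#' has fallen, around day 5.
#'
#' @param orp_scenario `"fast_drop"` or `"slow_drop"`.
#' @return List of [guild_spec()] objects whose baseline fractions sum to 1.
#' @export
default_guilds <- function(orp_scenario = c("fast_drop", "slow_drop")) {
  orp_scenario <- match.arg(orp_scenario)
  bg <- function(n, baseline, ...) {
    guild_spec("background",
               members = sprintf("otu_bg_%02d", seq_len(n)),
               genera = sprintf("Background_genus_%02d", seq_len(n)),
               baseline_fraction = baseline, ...)
  }
  if (orp_scenario == "fast_drop") {
    list(
      guild_spec("alkalibacterium",
                 c("otu_alkalibacterium_1", "otu_alkalibacterium_2"),
                 "Alkalibacterium", "early_riser", growth_rate = 0.25,
                 midpoint_day = 8, baseline_fraction = 0.28,
                 asymptote = 0.42, member_weights = c(0.7, 0.3),
                 reducer = TRUE),
      guild_spec("lactic", "otu_enterococcus_1", "Enterococcus",
                 "early_riser", growth_rate = 0.3, midpoint_day = 7,
                 baseline_fraction = 0.04, asymptote = 0.09, reducer = TRUE),
      guild_spec("anaerobes",
                 c("otu_alkalicella_1", "otu_tissierella_1",
                   "otu_amphibacillus_1"),
                 c("Alkalicella", "Tissierella", "Amphibacillus"),
                 "late_riser", growth_rate = 0.15, midpoint_day = 20,
                 baseline_fraction = 0.06, asymptote = 0.28,
                 member_weights = c(0.45, 0.3, 0.25), reducer = TRUE),
      guild_spec("actinomycetota",
                 c("otu_stackebrandtia_1", "otu_streptomyces_1"),
                 c("Stackebrandtia", "Streptomyces"), "decliner",
                 growth_rate = 3, midpoint_day = 1,
                 baseline_fraction = 0.012, asymptote = 0),
      bg(100, 0.608, trajectory_kind = "decliner", growth_rate = 0.08,
         midpoint_day = 25, asymptote = 0.04)
    )
  } else {
    list(
      guild_spec("bacillus", "otu_bacillus_1", "Bacillus", "decliner",
                 growth_rate = 0.8, midpoint_day = 4.5,
                 baseline_fraction = 0.14, asymptote = 0.01),
      guild_spec("actinomycetota",
                 c("otu_stackebrandtia_1", "otu_streptomyces_1"),
                 c("Stackebrandtia", "Streptomyces"), "decliner",
                 growth_rate = 0.6, midpoint_day = 5,
                 baseline_fraction = 0.10, asymptote = 0.005,
                 member_weights = c(0.6, 0.4)),
      guild_spec("alkalicella", "otu_alkalicella_1", "Alkalicella",
                 "early_riser", growth_rate = 0.9, midpoint_day = 4.5,
                 baseline_fraction = 0.004, asymptote = 0.40, reducer = TRUE),
      guild_spec("lactic", "otu_enterococcus_1", "Enterococcus",
                 "early_riser", growth_rate = 0.8, midpoint_day = 5,
                 baseline_fraction = 0.003, asymptote = 0.10, reducer = TRUE),
      guild_spec("alkalibacterium",
                 c("otu_alkalibacterium_1", "otu_alkalibacterium_2"),
                 "Alkalibacterium", "late_riser", growth_rate = 0.35,
                 midpoint_day = 12, baseline_fraction = 0.004,
                 asymptote = 0.30, member_weights = c(0.7, 0.3),
                 reducer = TRUE),
      guild_spec("amphibacillus", "otu_amphibacillus_1", "Amphibacillus",
                 "late_riser", growth_rate = 0.3, midpoint_day = 18,
                 baseline_fraction = 0.003, asymptote = 0.12, reducer = TRUE),
      bg(36, 0.55, trajectory_kind = "stable")
    )
  }
}

#' Synthetic dataset configuration
#'
#' Defaults mirror the two study designs: `fast_drop` samples 4 days
#' (3, 10, 27, 212) in duplicate at 20,000 reads/sample; `slow_drop` samples
#' 8 days (2, 5, 6, 7, 14, 29, 96, 200), in duplicate except day 5, at
#' 15,000 reads/sample. `noise_dispersion` is the Dirichlet concentration
#' scalar controlling within-day replicate variability (real vat surveys
#' rarely report replicate variability; the default of 2000 — about a 1% absolute
#' standard deviation on a 30% taxon — is a stated guess).
#'
#' @param orp_scenario `"fast_drop"` or `"slow_drop"`.
#' @param days Sampling days (strictly increasing).
#' @param replicates_per_day Scalar or per-day vector of replicate counts.
#' @param depth Reads per sample (> 0).
#' @param n_functions Number of gene families to simulate.
#' @param n_signal_functions Number planted with elevated copy number in
#'   reducer-guild genomes (`<= n_functions`).
#' @param noise_dispersion Dirichlet concentration scalar (larger = less
#'   replicate noise; `Inf` disables compositional noise).
#' @param seed Integer seed driving all randomness.
#' @param guilds List of [guild_spec()]s (default [default_guilds()]).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(orp_scenario = c("fast_drop", "slow_drop"),
                             days = NULL, replicates_per_day = NULL,
                             depth = NULL, n_functions = 300,
                             n_signal_functions = 30,
                             noise_dispersion = 2000, seed = 1,
                             guilds = NULL) {
  orp_scenario <- match.arg(orp_scenario)
  if (orp_scenario == "fast_drop") {
    days <- days %||% c(3, 10, 27, 212)
    depth <- depth %||% 20000L
  } else {
    days <- days %||% c(2, 5, 6, 7, 14, 29, 96, 200)
    depth <- depth %||% 15000L
    replicates_per_day <- replicates_per_day %||%
      ifelse(days == 5, 1L, 2L)
  }
  replicates_per_day <- replicates_per_day %||% 2L
  replicates_per_day <- rep_len(as.integer(replicates_per_day), length(days))
  if (length(days) == 0 || any(diff(days) <= 0)) {
    stop_input("synthetic_config: days must be nonempty and strictly increasing")
  }
  if (depth <= 0) stop_input("synthetic_config: depth must be > 0")
  if (n_signal_functions > n_functions) {
    stop_input("synthetic_config: n_signal_functions must be <= n_functions")
  }
  guilds <- guilds %||% default_guilds(orp_scenario)
  if (length(guilds) == 0) stop_input("synthetic_config: empty guild set")
  base_sum <- sum(vapply(guilds, function(g) g$baseline_fraction, numeric(1)))
  if (base_sum > 1 + 1e-9) {
    stop_invariant("synthetic_config: guild baseline fractions sum to > 1")
  }
  structure(list(orp_scenario = orp_scenario, days = days,
                 replicates_per_day = replicates_per_day,
                 depth = as.integer(depth), n_functions = n_functions,
                 n_signal_functions = n_signal_functions,
                 noise_dispersion = noise_dispersion, seed = as.integer(seed),
                 guilds = guilds),
            class = "synthetic_config")
}

# scenario ORP trajectories (mV); deterministic part
orp_curve <- function(orp_scenario, days) {
  if (orp_scenario == "fast_drop") {
    -620 - 30 * (1 - exp(-(days - 1) / 5))
  } else {
    -350 - 270 / (1 + exp(-(days - 3.5) * 2)) +
      60 / (1 + exp(-(days - 60) / 20))
  }
}

#' Simulate a synthetic fermentation dataset
#'
#' Builds the latent composition from the configured guild trajectories,
#' draws per-sample compositions from a Dirichlet perturbation
#' (concentration = `noise_dispersion` x latent composition; replicates
#' share a day's latent state and differ only by sampling noise), draws
#' counts multinomially at fixed depth, plants `n_signal_functions` gene
#' families with elevated copy numbers in reducer-guild genomes, and derives
#' the phenotype: scenario-specific ORP, mildly declining alkaline pH, and a
#' dyeing intensity that saturates in the reducer-guild fraction and is
#' gated by ORP at or below about -550 mV. The same seed yields a
#' bit-identical dataset.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_fermentation` list with elements `counts`,
#'   `metadata`, `taxonomy`, `genome_content`, `functions`, `stratified`,
#'   `hierarchy`, `latent`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_input("simulate_dataset: config must come from synthetic_config()")
  }
  guilds <- config$guilds
  days <- config$days
  otus <- unlist(lapply(guilds, `[[`, "members"))
  if (anyDuplicated(otus)) stop_input("simulate_dataset: duplicated taxon labels")
  genera <- unlist(lapply(guilds, `[[`, "genera"))

  # latent member-level composition per day, normalized across guilds
  latent <- do.call(rbind, lapply(guilds, function(g) {
    outer(g$member_weights, guild_trajectory(g, days))
  }))
  dimnames(latent) <- list(otus, paste0("day", days))
  latent <- sweep(latent, 2, colSums(latent), "/")

  sample_day <- rep(days, config$replicates_per_day)
  sample_rep <- unlist(lapply(config$replicates_per_day, seq_len))
  prefix <- if (config$orp_scenario == "fast_drop") "B" else "S"
  sample_ids <- sprintf("%s_d%03d_r%d", prefix, sample_day, sample_rep)

  # counts: Dirichlet-multinomial around the day's latent state
  set.seed(derive_seed(config$seed, "counts"))
  counts <- matrix(vapply(seq_along(sample_ids), function(i) {
    lam <- latent[, paste0("day", sample_day[i])]
    if (is.finite(config$noise_dispersion)) {
      alpha <- config$noise_dispersion * lam
      p <- numeric(length(lam))
      pos <- alpha > 0
      p[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
      p <- p / sum(p)
    } else {
      p <- lam
    }
    stats::rmultinom(1, config$depth, p)[, 1]
  }, integer(nrow(latent))), nrow = nrow(latent))
  dimnames(counts) <- list(otus, sample_ids)

  # genome content: copy numbers per (taxon, gene family)
  function_ids <- sprintf("KF%05d", seq_len(config$n_functions))
  reducer_otus <- unlist(lapply(guilds[vapply(guilds, `[[`, logical(1),
                                              "reducer")], `[[`, "members"))
  set.seed(derive_seed(config$seed, "genome"))
  signal <- sort(sample(function_ids, config$n_signal_functions))
  genome <- matrix(stats::rpois(length(otus) * config$n_functions,
                                lambda = 16),
                   nrow = length(otus),
                   dimnames = list(otus, function_ids))
  is_red <- otus %in% reducer_otus
  n_sig <- length(signal)
  genome[is_red, signal] <- 30L +
    matrix(stats::rpois(sum(is_red) * n_sig, 5), nrow = sum(is_red))
  genome[!is_red, signal] <- matrix(stats::rpois(sum(!is_red) * n_sig, 0.2),
                                    nrow = sum(!is_red))

  functions <- t(genome) %*% counts

  # stratified rows: exact product of abundance and copy number
  nz <- which(genome > 0, arr.ind = TRUE)
  strat <- do.call(rbind, lapply(seq_along(sample_ids), function(i) {
    ab <- counts[nz[, 1], i]
    keep <- ab > 0
    data.frame(Sample = sample_ids[i],
               Gene = function_ids[nz[keep, 2]],
               OTU = otus[nz[keep, 1]],
               GeneCountPerGenome = genome[nz[keep, , drop = FALSE]],
               OTUAbundanceInSample = ab[keep],
               CountContributedByOTU = genome[nz[keep, , drop = FALSE]] *
                 ab[keep],
               taxon = genera[nz[keep, 1]],
               stringsAsFactors = FALSE)
  }))
  rownames(strat) <- NULL

  # phenotype: ORP scenario, alkaline pH, gated saturating dyeing intensity
  set.seed(derive_seed(config$seed, "phenotype"))
  orp <- orp_curve(config$orp_scenario, sample_day) +
    stats::rnorm(length(sample_ids), sd = 3)
  if (config$orp_scenario == "fast_drop") {
    later <- sample_day > days[1]
    orp[later] <- pmin(orp[later], -601)
  } else {
    first <- sample_day == days[1]
    orp[first] <- pmax(orp[first], -395)
  }
  pH <- 10.35 + 0.3 * exp(-sample_day / 40) +
    stats::rnorm(length(sample_ids), sd = 0.03)
  reducer_frac_day <- colSums(latent[is_red, , drop = FALSE])
  frac <- reducer_frac_day[paste0("day", sample_day)]
  gate <- 1 / (1 + exp((orp + 550) / 8))
  intensity <- pmax(0, 0.45 + 2.1 * frac^2 / (frac^2 + 0.6^2) * gate +
                      stats::rnorm(length(sample_ids), sd = 0.05))

  metadata <- data.frame(
    sample_id = sample_ids, day = sample_day,
    batch = if (config$orp_scenario == "fast_drop") "big" else "small",
    replicate = paste0("r", sample_rep), pH = round(pH, 2),
    orp_mV = round(orp, 1), dyeing_intensity = round(intensity, 3),
    stringsAsFactors = FALSE)

  taxonomy <- data.frame(
    otu_id = otus,
    lineage = paste0("d__Bacteria;p__Synthetic;g__", genera),
    genus = genera, stringsAsFactors = FALSE)

  # hierarchy: signal families land in three reduction-associated
  # subpathways, background families cycle over generic ones
  signal_subs <- c("Prokaryotic defense system",
                   "Starch and sucrose metabolism",
                   "Replication, recombination and repair proteins")
  bg_subs <- sprintf("Generic subpathway %02d", 1:9)
  sub <- bg_subs[(seq_along(function_ids) - 1) %% 9 + 1]
  sub[function_ids %in% signal] <-
    signal_subs[(seq_len(n_sig) - 1) %% 3 + 1]
  hierarchy <- data.frame(
    function_id = function_ids, subpathway = sub,
    superpathway = ifelse(function_ids %in% signal,
                          "Indigo reduction associated", "Generic"),
    category = "Synthetic", stringsAsFactors = FALSE)

  structure(list(
    counts = counts, metadata = metadata, taxonomy = taxonomy,
    genome_content = genome, functions = functions, stratified = strat,
    hierarchy = hierarchy, latent = latent,
    truth = list(signal_functions = signal,
                 background_functions = setdiff(function_ids, signal),
                 reducer_otus = reducer_otus,
                 reducer_genera = unique(genera[is_red]),
                 guild_names = vapply(guilds, `[[`, character(1), "name")),
    config = config), class = "synthetic_fermentation")
}

#' @export
print.synthetic_fermentation <- function(x, ...) {
  cat("Synthetic fermentation dataset (", x$config$orp_scenario, "): ",
      nrow(x$counts), " taxa x ", ncol(x$counts), " samples, depth ",
      x$config$depth, ", ", x$config$n_functions, " gene families (",
      length(x$truth$signal_functions), " signal)\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the count table, metadata, taxonomy, function table, stratified
#' contributions, hierarchy map and truth record as tab-delimited text.
#'
#' @param dataset A `synthetic_fermentation` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_count_table(dataset$counts, p("counts.tsv"))
  write_sample_metadata(dataset$metadata, p("metadata.tsv"))
  utils::write.table(dataset$taxonomy[c("otu_id", "lineage")],
                     p("taxonomy.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_function_table(dataset$functions, p("functions.tsv"))
  write_stratified(dataset$stratified, p("stratified.tsv"))
  utils::write.table(dataset$hierarchy, p("hierarchy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- data.frame(function_id = c(dataset$truth$signal_functions,
                                      dataset$truth$background_functions),
                      planted_signal = rep(c(TRUE, FALSE),
                                           c(length(dataset$truth$signal_functions),
                                             length(dataset$truth$background_functions))),
                      stringsAsFactors = FALSE)
  utils::write.table(truth[order(truth$function_id), ], p("truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}
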