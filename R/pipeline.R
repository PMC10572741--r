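# Pipeline orchestration: wire the generator (or user-supplied tables)
# through diversity, the functional screen, network inference and the EET
# genome scan, with reproducible seeds and provenance headers.

#' Read a pipeline run configuration
#'
#' YAML with optional blocks: `simulate` (generator settings: `scenario`,
#' `days`, `depth`, ...), `inputs` (paths: `counts`, `metadata`, `taxonomy`,
#' `functions`, `stratified`, `hierarchy`, `gff`), `thresholds`
#' (`select`, `highlight`, `correlation`, `rs`, `alpha`, `prevalence`,
#' `rarefaction_depth`, `max_gap_genes`, `e_required_mV`), `seed` and
#' `out_dir`. Anything omitted falls back to the package defaults
#' (thresholds 1.05, 1.4, 0.9, 0.6, 0.05, 0.02).
#'
#' @param path Path to a YAML file.
#' @return A named configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file '", path, "' not found")
  yaml::read_yaml(path)
}

default_thresholds <- function() {
  list(select = 1.05, highlight = 1.4, correlation = 0.9, rs = 0.6,
       alpha = 0.05, prevalence = 0.02, rarefaction_depth = NULL,
       max_gap_genes = 10, e_required_mV = -600)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(config, seed) {
  ver <- as.character(utils::packageVersion("indigoferm"))
  sprintf("# indigoferm %s\tseed=%s\tconfig=%s", ver, seed,
          config_hash(config))
}

emit <- function(path, header, write_fun) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_fun(tmp)
  writeLines(c(header, readLines(tmp)), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when no input tables are configured) -> alpha
#' diversity -> subpathway ratios + CLR-correlation screen -> co-occurrence
#' network -> EET genome scan (when a GFF3 is configured), writing
#' tab-delimited reports into `out_dir`. Every report starts with a
#' provenance comment (package version, seed, configuration hash); the same
#' configuration and seed reproduce byte-identical outputs. Any stage
#' failure aborts with the stage name attached to the error message.
#'
#' @param config Configuration list (see [read_run_config()]) or a path to a
#'   YAML file.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a named list of the report paths written.
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop_input("run_all: no out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  header <- provenance_header(config, seed)
  paths <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(errorCondition(
        paste0("stage '", name, "' failed: ", conditionMessage(e)),
        class = class(e)[class(e) != "simpleError"]))
    })
  }

  inputs <- config$inputs %||% list()
  if (length(inputs) == 0 || !is.null(config$simulate)) {
    sim <- config$simulate %||% list()
    dataset <- stage("simulate", function() {
      cfg <- synthetic_config(
        orp_scenario = sim$scenario %||% "fast_drop",
        days = sim$days, depth = sim$depth,
        replicates_per_day = sim$replicates_per_day,
        n_functions = sim$n_functions %||% 300,
        n_signal_functions = sim$n_signal_functions %||% 30,
        noise_dispersion = sim$noise_dispersion %||% 2000,
        seed = seed)
      simulate_dataset(cfg)
    })
    data_dir <- file.path(out_dir, "data")
    write_dataset(dataset, data_dir)
    counts <- dataset$counts
    metadata <- dataset$metadata
    taxonomy <- dataset$taxonomy
    functions <- dataset$functions
    strat <- dataset$stratified
    hierarchy <- dataset$hierarchy
    paths$data <- data_dir
  } else {
    counts <- stage("inputs", function() read_count_table(inputs$counts))
    metadata <- stage("inputs", function() read_sample_metadata(inputs$metadata))
    taxonomy <- if (!is.null(inputs$taxonomy))
      stage("inputs", function() read_taxonomy(inputs$taxonomy)) else NULL
    functions <- if (!is.null(inputs$functions))
      stage("inputs", function() read_function_table(inputs$functions)) else NULL
    hierarchy <- if (!is.null(inputs$hierarchy))
      stage("inputs", function() read_hierarchy(inputs$hierarchy)) else NULL
    strat <- if (!is.null(inputs$stratified))
      stage("inputs", function() read_stratified(inputs$stratified, taxonomy))
      else NULL
  }

  # alpha diversity at a fixed depth
  div <- stage("diversity", function() {
    depth <- thr$rarefaction_depth %||% min(colSums(counts))
    alpha_diversity(counts, depth, seed)
  })
  paths$diversity <- emit(file.path(out_dir, "diversity.tsv"), header,
    function(f) utils::write.table(div, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE))

  # functional screen
  if (!is.null(functions) && !is.null(hierarchy)) {
    screen <- stage("screen", function() {
      profiles <- subpathway_percentages(functions, hierarchy)
      sample_days <- metadata$day[match(colnames(profiles),
                                        metadata$sample_id)]
      pairs <- config$screen$pairs %||% default_day_pairs(metadata)
      ratios <- ratio_select(profiles, sample_days, pairs,
                             select_threshold = thr$select,
                             highlight_threshold = thr$highlight)
      clr <- clr_transform(functions)
      phen <- stats::setNames(metadata$dyeing_intensity, metadata$sample_id)
      corr <- correlate_with_phenotype(clr, phen, threshold = thr$correlation)
      list(ratios = ratios, corr = corr)
    })
    paths$ratios <- emit(file.path(out_dir, "subpathway_ratios.tsv"), header,
      function(f) utils::write.table(screen$ratios, f, sep = "\t",
                                     quote = FALSE, row.names = FALSE))
    paths$screen <- emit(file.path(out_dir, "screen.tsv"), header,
      function(f) utils::write.table(screen$corr, f, sep = "\t",
                                     quote = FALSE, row.names = FALSE))
  }

  # co-occurrence network
  net <- stage("network", function() {
    rel <- filter_prevalent(to_relative(counts), thr$prevalence)
    traj <- build_trajectories(rel, taxonomy, metadata)
    build_network(traj, rs_threshold = thr$rs, alpha = thr$alpha)
  })
  paths$network <- file.path(out_dir, "network_edges.tsv")
  write_edge_list(net, paths$network)
  write_graphml(net, file.path(out_dir, "network.graphml"))

  # EET genome scan
  if (!is.null(inputs$gff)) {
    report <- stage("eetscan", function() {
      eet_scan(inputs$gff, max_gap_genes = thr$max_gap_genes)
    })
    paths$eet <- file.path(out_dir, "eet_report.tsv")
    write_eet_report(report, paths$eet)
  }

  invisible(paths)
}

# numerator days = the two days of highest mean dyeing intensity,
# denominator = the final (aged) sampling day
default_day_pairs <- function(metadata) {
  by_day <- tapply(metadata$dyeing_intensity, metadata$day, mean)
  days <- as.numeric(names(by_day))
  den <- max(days)
  cand <- days[days != den]
  num <- cand[order(-by_day[as.character(cand)])][1:min(2, length(cand))]
  lapply(sort(num), function(d) c(d, den))
}
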