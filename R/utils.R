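# Internal condition helpers. Three classes mirror the package's exit codes:
# input/format problems (code 2) vs invariant violations (code 3).

stop_input <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("indigoferm_input_error", "indigoferm_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("indigoferm_format_error", "indigoferm_input_error",
              "indigoferm_error")))
}

stop_invariant <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("indigoferm_invariant_error", "indigoferm_error")))
}

# Derive a per-stage RNG seed from the global one, keeping the result a
# valid 32-bit integer.
derive_seed <- function(seed, stage) {
  offsets <- c(counts = 11L, phenotype = 23L, genome = 37L, noise = 53L,
               rarefy = 71L, generic = 97L)
  off <- offsets[[stage]] %||% offsets[["generic"]]
  as.integer((as.numeric(seed) * 1000003 + off * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_file <- function(path, what) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop_input(what, " file '", paste(path, collapse = ","), "' not found")
  }
  invisible(path)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}
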