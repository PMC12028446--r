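# Internal utilities: local RNG scope, seed derivation, CSV with metadata
# headers, and a small string hash for config provenance.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so library functions never disturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic counter scheme: every pipeline stage (and every synthetic
#' trial) gets its own reproducible seed from one master seed, so stages can
#' be re-run independently. Arithmetic is done modulo the Mersenne prime
#' 2^31 - 1 to stay within R's integer range.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integer counters identifying the
#'   stage or sub-stream.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (k in as.numeric(c(...))) {
    # multiply-mix; 48271 is the MINSTD multiplier, products stay < 2^53
    h <- (h * 48271 + k + 1) %% m
  }
  as.integer(h + 1)
}

# Stage counters for the pipeline's seed fan-out (documented scheme).
.stage_counters <- c(
  simulate = 11L, split = 23L, init = 37L, permute = 53L
)

stage_seed <- function(master, stage) {
  derive_seed(master, .stage_counters[[stage]])
}

#' Tiny string hash for provenance stamping
#'
#' Polynomial rolling hash over UTF-8 bytes modulo 2^31 - 1. Not
#' cryptographic; used only to stamp output files with a configuration
#' fingerprint.
#'
#' @param x character scalar (or object, which is deparsed).
#' @return hexadecimal string.
#' @keywords internal
#' @noRd
config_hash <- function(x) {
  if (!is.character(x)) x <- paste(deparse(x), collapse = "\n")
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

#' Write a data frame as CSV with a commented metadata header
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named character vector written as `# key: value` lines.
#' @keywords internal
#' @noRd
write_csv_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_meta()], skipping `#` metadata lines
#' @keywords internal
#' @noRd
read_csv_meta <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
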