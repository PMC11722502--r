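# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a role label
#'
#' One master seed fans out to per-output sub-seeds through a fixed string
#' hash, so adding a new output file never reshuffles the randomness of
#' existing ones. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param role Character scalar naming the output (e.g. `"genome"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, role) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(role))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- abs(as.numeric(seed)) %% m
  for (b in utf8ToInt(role)) h <- (h * 131 + b) %% m
  as.integer(h)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers over [data.table::fread()] / [data.table::fwrite()] that fix
#' the dialect used by every text interface in this package: tab-separated,
#' header row, no quoting, plain `data.frame` in and out.
#'
#' @param path File path.
#' @param x A data.frame.
#' @param col.names Write a header row (`FALSE` for headerless formats such
#'   as rmap/baitmap/BED).
#' @return `read_tsv()` returns a `data.frame`; `write_tsv()` returns `path`
#'   invisibly.
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = c("NA", "")))
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path, col.names = TRUE) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE,
                     col.names = col.names, na = "NA")
  invisible(path)
}

# Convert 0-based half-open intervals to an IRanges (1-based closed).
.ir_from_0based <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

# Collapse a character vector to a comma string; NA for empty.
.collapse <- function(x) {
  if (length(x) == 0L) NA_character_ else paste(sort(unique(x)), collapse = ",")
}

# Split a comma string back to a character vector (zero-length for NA).
.uncollapse <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ",", fixed = TRUE)[[1]]
}

# Stage-tagged condition used by run_pipeline().
.stage_error <- function(stage, e) {
  stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
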