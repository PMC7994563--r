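#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers are returned numeric, comma-separated values as vectors.
#' Recognized generator keys (`n_classes`, `n_features`, `class_separation`,
#' `within_spread`, `n_instances`, `seed`) feed [as_generator_config()];
#' extra keys (experiment grids etc.) are passed through untouched.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}

#' Build a generator configuration from a parsed config list
#'
#' @param conf named list as returned by [read_config()]; unknown keys are
#'   ignored.
#' @return A [generator_config()].
#' @export
as_generator_config <- function(conf) {
  args <- conf[intersect(names(conf),
                         c("n_classes", "n_features", "class_separation",
                           "within_spread", "n_instances", "seed"))]
  do.call(generator_config, args)
}
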