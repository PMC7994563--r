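# Independent brute-force reference for the kernel, representing a relation
# as an explicit set of (arg, level) pairs: abstraction is set union,
# containment a subset test per argument, entropy counts pairs per argument,
# and reduction enumerates each argument's candidate set directly. Used to
# cross-check the dense table implementation on random instances.

oracle_new <- function(n_args, n_levels, pairs) {
  # pairs: two-column matrix (arg 1-based, level 0-based); may be empty
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  pairs <- unique(pairs)
  list(n_args = n_args, n_levels = n_levels, pairs = pairs)
}

oracle_from_relation <- function(r) {
  idx <- which(r$cells, arr.ind = TRUE)
  oracle_new(ncol(r$cells), nrow(r$cells),
             cbind(idx[, "col"], idx[, "row"] - 1L))
}

oracle_to_relation <- function(o) {
  relation(o$n_args, o$n_levels,
           marks = if (nrow(o$pairs)) o$pairs else NULL)
}

pair_keys <- function(o) {
  if (nrow(o$pairs) == 0L) character(0) else paste(o$pairs[, 1L], o$pairs[, 2L])
}

oracle_abstraction <- function(a, b) {
  oracle_new(a$n_args, a$n_levels, rbind(a$pairs, b$pairs))
}

oracle_containment <- function(ra, rf, relax = 0L) {
  extra <- setdiff(pair_keys(ra), pair_keys(rf))
  failed <- length(unique(vapply(strsplit(extra, " "), `[`, character(1L), 1L)))
  list(accept = failed <= relax, failed_args = failed)
}

oracle_entropy <- function(o) {
  mu <- tabulate(o$pairs[, 1L], nbins = o$n_args)
  mean(ifelse(mu > 0L, log2(mu), 0))
}

oracle_support <- function(o, i) sort(o$pairs[o$pairs[, 1L] == i, 2L])

# identity-mode reduction by direct candidate enumeration
oracle_reduction_identity <- function(f, o, relax = 0L) {
  fo <- oracle_from_relation(function_to_relation(f))
  if (!oracle_containment(fo, o, relax)$accept) return(NULL)
  lv <- unclass(f)
  out <- rep(NA_integer_, o$n_args)
  for (i in seq_len(o$n_args)) {
    s <- oracle_support(o, i)
    if (length(s) == 0L) next
    centre <- if (!is.na(lv[i])) lv[i] else s[ceiling(length(s) / 2)]
    out[i] <- if (!is.na(lv[i]) && lv[i] %in% s) lv[i] else s[which.min(abs(s - centre))]
  }
  discrete_fn(out, o$n_levels)
}

# random instance generators used across property tests
random_relation <- function(n_args, n_levels, p = 0.3) {
  cells <- matrix(stats::runif(n_args * n_levels) < p,
                  nrow = n_levels, ncol = n_args)
  eamem:::new_relation(cells)
}

random_fn <- function(n_args, n_levels, p_missing = 0.2) {
  lv <- sample.int(n_levels, n_args, replace = TRUE) - 1L
  lv[stats::runif(n_args) < p_missing] <- NA_integer_
  discrete_fn(lv, n_levels)
}
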