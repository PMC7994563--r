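#' Configuration for the synthetic feature-corpus generator
#'
#' The generator emulates the latent feature vectors a trained convolutional
#' encoder would produce for images of handwritten digits: class-conditional,
#' unimodal real-valued vectors. Each class gets a mean vector drawn once;
#' instances add independent Gaussian noise of scale `within_spread`. Class
#' mean coordinates are drawn from a centred normal whose scale is chosen so
#' that the expected per-feature separation between two class means equals
#' `class_separation * within_spread`.
#'
#' @param n_classes number of classes (default 10, one per digit).
#' @param n_features features per instance (default 64, the encoder width).
#' @param class_separation distance between class means in units of
#'   within-class spread (default 6: well separated, the regime where a
#'   32-level quantization gives near-disjoint class level sets).
#' @param within_spread within-class standard deviation (default 1).
#' @param n_instances total corpus size (default 4000, balanced; 400 per
#'   class keeps a 1% share of each class's rem split at a whole instance,
#'   so the fill-fraction sweep of [run_experiment3()] stays meaningful).
#' @param fractions named train/rem/test split fractions, summing to 1
#'   (default 0.57/0.33/0.10).
#' @param seed integer seed; the corpus is a deterministic function of the
#'   configuration.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_classes = 10L, n_features = 64L,
                             class_separation = 6, within_spread = 1,
                             n_instances = 4000L,
                             fractions = c(train = 0.57, rem = 0.33, test = 0.10),
                             seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              n_features = as.integer(n_features),
              class_separation = as.numeric(class_separation),
              within_spread = as.numeric(within_spread),
              n_instances = as.integer(n_instances),
              fractions = fractions,
              seed = as.integer(seed))
  stopifnot(cfg$n_classes >= 1L, cfg$n_features >= 1L,
            cfg$class_separation >= 0, cfg$within_spread > 0,
            cfg$n_instances >= cfg$n_classes,
            length(cfg$fractions) == 3L,
            abs(sum(cfg$fractions) - 1) < 1e-9)
  structure(cfg, class = "generator_config")
}

# Balanced per-class counts; any remainder goes to the first classes.
balanced_counts <- function(n_instances, n_classes) {
  base <- n_instances %/% n_classes
  counts <- rep(base, n_classes)
  extra <- n_instances - base * n_classes
  if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

#' Generate a labelled synthetic feature corpus
#'
#' @param cfg a [generator_config()].
#' @return A data frame with columns `id`, `label` (character class names
#'   `"0" ..`), and `f0 .. f{n-1}` numeric features.
#' @examples
#' corpus <- generate_corpus(generator_config(n_instances = 100))
#' table(corpus$label)
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  counts <- balanced_counts(cfg$n_instances, cfg$n_classes)
  mean_sd <- cfg$class_separation * cfg$within_spread / sqrt(2)
  with_seed(cfg$seed, {
    means <- matrix(stats::rnorm(cfg$n_classes * cfg$n_features, sd = mean_sd),
                    nrow = cfg$n_classes)
    blocks <- lapply(seq_len(cfg$n_classes), function(k) {
      noise <- matrix(stats::rnorm(counts[k] * cfg$n_features,
                                   sd = cfg$within_spread),
                      nrow = counts[k])
      sweep(noise, 2L, means[k, ], "+")
    })
  })
  x <- do.call(rbind, blocks)
  labels <- rep(as.character(seq_len(cfg$n_classes) - 1L), counts)
  out <- data.frame(id = sprintf("i%05d", seq_len(nrow(x))),
                    label = labels, stringsAsFactors = FALSE)
  colnames(x) <- paste0("f", seq_len(cfg$n_features) - 1L)
  cbind(out, as.data.frame(x))
}

#' Feature matrix of a corpus
#' @param corpus a corpus data frame from [generate_corpus()] or
#'   [read_corpus()].
#' @return Numeric matrix, instances by features.
#' @export
corpus_features <- function(corpus) {
  as.matrix(corpus[, grep("^f[0-9]+$", names(corpus)), drop = FALSE])
}

#' Partition a corpus into train / rem / test splits
#'
#' Class-stratified, disjoint and exhaustive. Within each class, instances
#' are shuffled once under `seed`; rotating `fold` shifts which contiguous
#' block of that fixed shuffle lands in each split, giving a 10-fold style
#' rotation. Split sizes follow the fractions by largest remainder, so each
#' per-class count is within one instance of the exact share.
#'
#' @param corpus a corpus data frame.
#' @param fractions train/rem/test fractions summing to 1.
#' @param fold rotation index in `0 .. 9`.
#' @param seed seed of the fixed per-class shuffle.
#' @return The corpus with an added `split` column in
#'   `c("train", "rem", "test")`.
#' @export
partition_corpus <- function(corpus, fractions = c(0.57, 0.33, 0.10),
                             fold = 0L, seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  fold <- as.integer(fold)
  if (fold < 0L || fold > 9L) stop("fold must be in 0..9")
  split <- rep(NA_character_, nrow(corpus))
  with_seed(seed, {
    for (cl in unique(corpus$label)) {
      idx <- which(corpus$label == cl)
      n <- length(idx)
      idx <- idx[sample.int(n)]
      shift <- (round(fold * n / 10L)) %% n
      if (shift > 0L) idx <- c(idx[(shift + 1L):n], idx[seq_len(shift)])
      counts <- largest_remainder(fractions, n)
      tags <- rep(c("train", "rem", "test"), counts)
      split[idx] <- tags
    }
  })
  corpus$split <- split
  corpus
}

# Integer apportionment: floor shares, remainder to the largest fractional
# parts (ties resolved in train/rem/test order).
largest_remainder <- function(fractions, n) {
  exact <- fractions * n
  counts <- floor(exact)
  left <- n - sum(counts)
  if (left > 0L) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1L
  }
  as.integer(counts)
}

#' Occlude a feature vector
#'
#' Feature-space analogue of occluding part of an input image: a chosen
#' fraction of feature indices is either marked missing (`mode = "missing"`,
#' the information is absent) or replaced by draws from a pooled all-class
#' marginal (`mode = "background"`, the information is corrupted). The two
#' modes bracket how an encoder might respond to occluded pixels.
#'
#' Patterns: `"prefix"` affects the first `floor(fraction * n)` indices;
#' `"bars"` affects alternating blocks of `bar_width` consecutive features
#' (starting with the first block) until the count is reached; `"random"`
#' affects a seeded random subset.
#'
#' @param v numeric feature vector.
#' @param mode `"missing"` or `"background"`.
#' @param fraction fraction of features to affect, in `[0, 1]`.
#' @param pattern `"prefix"`, `"bars"` or `"random"`.
#' @param seed seed for the random pattern and the background draws.
#' @param pool numeric matrix (instances x features) whose columns supply the
#'   background marginal; required for `mode = "background"`.
#' @param bar_width block width of the `"bars"` pattern (default 4).
#' @return The occluded vector (`NA` marks missing features).
#' @export
occlude <- function(v, mode = c("missing", "background"), fraction,
                    pattern = c("prefix", "bars", "random"), seed = 1L,
                    pool = NULL, bar_width = 4L) {
  mode <- match.arg(mode)
  pattern <- match.arg(pattern)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- length(v)
  k <- floor(fraction * n)
  if (k == 0L) return(v)
  if (mode == "background") {
    if (is.null(pool)) stop("mode = 'background' requires a feature pool")
    pool <- as.matrix(pool)
    if (ncol(pool) != n) stop_mismatch("pool columns and vector length differ")
  }
  with_seed(seed, {
    idx <- switch(pattern,
      prefix = seq_len(k),
      bars = {
        block <- (seq_len(n) - 1L) %/% as.integer(bar_width)
        cand <- c(which(block %% 2L == 0L), which(block %% 2L == 1L))
        cand[seq_len(k)]
      },
      random = sample.int(n, k))
    if (mode == "missing") {
      v[idx] <- NA_real_
    } else {
      v[idx] <- vapply(idx, function(i) {
        pool[sample.int(nrow(pool), 1L), i]
      }, numeric(1L))
    }
  })
  v
}

#' Write a corpus to the delimited feature-table format
#'
#' CSV with header `id,label,f0,...,f{n-1}`, one instance per line, missing
#' values as empty fields. The `split` column, if present, is not written.
#'
#' @param corpus a corpus data frame.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  cols <- c("id", "label", grep("^f[0-9]+$", names(corpus), value = TRUE))
  utils::write.csv(corpus[, cols], path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' Read a corpus written by [write_corpus()]
#' @param path file path.
#' @return A corpus data frame with character `id`/`label` and numeric
#'   features.
#' @export
read_corpus <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(id = "character", label = "character"))
  fcols <- grep("^f[0-9]+$", names(out), value = TRUE)
  for (cl in fcols) out[[cl]] <- as.numeric(out[[cl]])
  out
}
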