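# Desk-scale analogues of the five memory experiments: granularity sweep,
# overlapped registers, fill-fraction sweep, constructive retrieval
# similarity, and recognition of occluded cues under relaxation.

# Fit the quantizer on the train split and fill registers from the rem split.
# `register_map` maps register label -> character vector of member classes;
# default one register per class. `rem_take` caps how many rem instances per
# class are registered (NULL = all, in split order).
build_bank <- function(part, m_bits, relax = 0L, register_map = NULL,
                       rem_take = NULL) {
  feats <- corpus_features(part)
  q <- fit_quantizer(feats[part$split == "train", , drop = FALSE], m_bits)
  if (is.null(register_map)) {
    cls <- sort(unique(part$label))
    register_map <- stats::setNames(as.list(cls), cls)
  }
  bank <- register_bank(names(register_map), q, relax = relax)
  rem <- which(part$split == "rem")
  for (lb in names(register_map)) {
    idx <- rem[part$label[rem] %in% register_map[[lb]]]
    if (!is.null(rem_take)) {
      take <- unlist(lapply(register_map[[lb]], function(cl) {
        sub <- idx[part$label[idx] == cl]
        sub[seq_len(min(rem_take, length(sub)))]
      }))
      idx <- take
    }
    if (length(idx) == 0L) next
    lv <- quantize_levels(feats[idx, , drop = FALSE], q)
    cells <- bank$registers[[lb]]$table$cells
    for (j in seq_len(ncol(lv))) {
      seen <- unique(lv[, j])
      seen <- seen[!is.na(seen)]
      if (length(seen)) cells[seen + 1L, j] <- TRUE
    }
    bank$registers[[lb]]$table <- new_relation(cells)
    bank$registers[[lb]]$registered_count <- length(idx)
  }
  bank
}

# Vectorized recognition of a level matrix (instances x features) against one
# register table; returns the failed-column count per instance. Equivalent to
# one containment() call per (instance, register) — verified in the tests.
failed_counts <- function(cells, lv) {
  n_lv <- nrow(cells)
  hit <- matrix(cells[(col(lv) - 1L) * n_lv + lv + 1L],
                nrow = nrow(lv), ncol = ncol(lv))
  rowSums(!hit, na.rm = TRUE)
}

bank_failed_matrix <- function(bank, lv) {
  vapply(bank$registers, function(reg) failed_counts(reg$table$cells, lv),
         numeric(nrow(lv)))
}

bank_entropies <- function(bank) {
  vapply(bank$registers, function(reg) ric_entropy(reg$table), numeric(1L))
}

# Minimal-entropy decision among accepting registers; NA = rejection.
# selection = "random" draws uniformly among acceptors instead (seeded by
# the caller).
decide_labels <- function(accepts, entropies, labels,
                          selection = c("min_entropy", "random")) {
  selection <- match.arg(selection)
  apply(accepts, 1L, function(a) {
    acc <- which(a)
    if (length(acc) == 0L) return(NA_character_)
    if (selection == "random") return(labels[acc[sample.int(length(acc), 1L)]])
    labels[acc[which.min(entropies[acc])]]
  })
}

metrics_row <- function(experiment, m_bits, fill_fraction, relax, occlusion,
                        reg, ent_mean, sys, accepting_mean,
                        similarity_mean = NA_real_) {
  data.frame(experiment = experiment, m_bits = m_bits,
             fill_fraction = fill_fraction, relax = relax,
             occlusion = occlusion,
             precision_reg = reg$precision, recall_reg = reg$recall,
             entropy_bits = ent_mean,
             precision_sys = sys$precision, recall_sys = sys$recall,
             rejection_rate = sys$rejection_rate,
             all_rejected = sys$all_rejected,
             accepting_mean = accepting_mean,
             similarity_mean = similarity_mean,
             stringsAsFactors = FALSE)
}

evaluate_bank <- function(bank, part, experiment, m_bits, fill_fraction = 1,
                          relax = bank$relax, occlusion = "none",
                          test_feats = NULL, average = "macro",
                          selection = "min_entropy") {
  feats <- corpus_features(part)
  test <- which(part$split == "test")
  if (is.null(test_feats)) test_feats <- feats[test, , drop = FALSE]
  lv <- quantize_levels(test_feats, bank$quantizer)
  failed <- bank_failed_matrix(bank, lv)
  accepts <- failed <= relax
  ent <- bank_entropies(bank)
  reg <- per_register_metrics(accepts, part$label[test], bank_labels(bank),
                              average = average)
  decisions <- decide_labels(accepts, ent, bank_labels(bank), selection)
  sys <- system_metrics(decisions, part$label[test])
  metrics_row(experiment, m_bits, fill_fraction, relax, occlusion, reg,
              mean(ent), sys, mean(rowSums(accepts)))
}

#' Granularity sweep: register characteristics across bit depths
#'
#' Builds, for each `m` in `m_grid`, a bank of one register per class with
#' `64 x 2^m` tables, fills it with the rem split, and evaluates recognition
#' and minimal-entropy retrieval on the test split. At `m = 0` every
#' register has a single row, all information is confused, and the run is
#' structurally forced to mean per-register precision `1/n_classes`, recall
#' 1, acceptance by every register, and zero entropy.
#'
#' @param cfg a [generator_config()].
#' @param m_grid integer bit depths to sweep (default `0:9`).
#' @param fold partition rotation index (default 0).
#' @param average per-register averaging, `"macro"` or `"micro"`.
#' @param selection decision rule among accepting registers,
#'   `"min_entropy"` (default) or `"random"` (uniform, seeded from `cfg`).
#' @return A data frame with one metrics row per `m`.
#' @export
run_experiment1 <- function(cfg, m_grid = 0:9, fold = 0L, average = "macro",
                            selection = "min_entropy") {
  part <- partition_corpus(generate_corpus(cfg), fold = fold, seed = cfg$seed)
  rows <- lapply(m_grid, function(m) {
    bank <- build_bank(part, m)
    if (selection == "random") {
      with_seed(cfg$seed + 211L + m,
                evaluate_bank(bank, part, "exp1", m, average = average,
                              selection = "random"))
    } else {
      evaluate_bank(bank, part, "exp1", m, average = average)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Overlapped registers: two classes per register
#'
#' Same sweep as [run_experiment1()] but each register holds the distributed
#' representation of a pair of classes. The per-`m` rows also carry the mean
#' entropy of the corresponding single-class bank (`entropy_single_bits`),
#' which the overlapped entropy exceeds whenever the pairs differ.
#'
#' @param cfg a [generator_config()].
#' @param pairing list of class-label pairs; default consecutive digits
#'   `("0","1"), ("2","3"), ...`.
#' @param m_grid integer bit depths to sweep.
#' @param fold partition rotation index.
#' @return A data frame with one metrics row per `m`.
#' @export
run_experiment2 <- function(cfg, pairing = NULL, m_grid = 0:9, fold = 0L) {
  part <- partition_corpus(generate_corpus(cfg), fold = fold, seed = cfg$seed)
  cls <- sort(unique(part$label))
  if (is.null(pairing)) {
    stopifnot(length(cls) %% 2L == 0L)
    pairing <- split(cls, rep(seq_len(length(cls) / 2L), each = 2L))
  }
  register_map <- stats::setNames(
    lapply(pairing, as.character),
    vapply(pairing, function(p) paste(p, collapse = "+"), character(1L)))
  rows <- lapply(m_grid, function(m) {
    bank <- build_bank(part, m, register_map = register_map)
    single <- build_bank(part, m)
    row <- evaluate_bank(bank, part, "exp2", m)
    row$entropy_single_bits <- mean(bank_entropies(single))
    row
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fill-fraction sweep at fixed granularity
#'
#' Fills the registers with increasing proportions of the rem split (at
#' least one instance per class) at a fixed bit depth — default `m = 5`,
#' the `64 x 32` geometry chosen for economy — and evaluates the test split.
#' Entropy grows with the amount of remembered data; recall grows with it
#' while precision stays high.
#'
#' @param cfg a [generator_config()].
#' @param fill_fractions proportions of the rem split to register.
#' @param m_bits fixed bit depth (default 5).
#' @param fold partition rotation index.
#' @return A data frame with one metrics row per fill fraction.
#' @export
run_experiment3 <- function(cfg,
                            fill_fractions = c(0.01, 0.02, 0.04, 0.08,
                                               0.16, 0.32, 0.64, 1),
                            m_bits = 5L, fold = 0L) {
  part <- partition_corpus(generate_corpus(cfg), fold = fold, seed = cfg$seed)
  n_rem_class <- min(table(part$label[part$split == "rem"]))
  rows <- lapply(fill_fractions, function(fr) {
    take <- max(1L, floor(fr * n_rem_class))
    bank <- build_bank(part, m_bits, rem_take = take)
    evaluate_bank(bank, part, "exp3", m_bits, fill_fraction = fr)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Constructive-retrieval similarity across entropy levels
#'
#' Measures how the indeterminacy of the registers degrades the resemblance
#' between a cue and the object constructed from it. For each fill fraction
#' the bank is filled as in [run_experiment3()]; the retrieval cues are the
#' first rem instance of every class, which — the fills being nested — are
#' registered (hence accepted) at every fill level, so the same cues are
#' followed across the whole entropy range. Each cue is retrieved
#' `n_draws` times under the triangular policy and the similarity between
#' the cue and the constructed object is averaged.
#'
#' @param cfg a [generator_config()].
#' @param fill_fractions proportions of the rem split to register.
#' @param m_bits fixed bit depth (default 5).
#' @param fold partition rotation index.
#' @param n_draws triangular retrievals per cue and fill level (default 10).
#' @param policy_seed seed of the triangular policy stream (default derived
#'   from `cfg`).
#' @return A data frame with one metrics row per fill fraction;
#'   `similarity_mean` is the mean over cues and draws.
#' @export
run_experiment4 <- function(cfg,
                            fill_fractions = c(0.01, 0.02, 0.04, 0.08,
                                               0.16, 0.32, 0.64, 1),
                            m_bits = 5L, fold = 0L, n_draws = 10L,
                            policy_seed = cfg$seed + 401L) {
  part <- partition_corpus(generate_corpus(cfg), fold = fold, seed = cfg$seed)
  feats <- corpus_features(part)
  rem <- which(part$split == "rem")
  cues <- vapply(sort(unique(part$label)), function(cl) {
    rem[part$label[rem] == cl][1L]
  }, integer(1L))
  n_rem_class <- min(table(part$label[part$split == "rem"]))
  policy <- reduction_policy("triangular", seed = policy_seed)
  rows <- lapply(fill_fractions, function(fr) {
    take <- max(1L, floor(fr * n_rem_class))
    bank <- build_bank(part, m_bits, rem_take = take)
    row <- evaluate_bank(bank, part, "exp4", m_bits, fill_fraction = fr)
    lv <- quantize_levels(feats[cues, , drop = FALSE], bank$quantizer)
    sims <- unlist(lapply(seq_along(cues), function(i) {
      cue <- discrete_fn(lv[i, ], bank$quantizer$n_levels)
      table_i <- bank$registers[[part$label[cues[i]]]]$table
      vapply(seq_len(n_draws), function(d) {
        out <- reduction(cue, table_i, policy = policy, relax = bank$relax)
        cue_similarity(feats[cues[i], ], dequantize(out, bank$quantizer),
                       bank$quantizer)
      }, numeric(1L))
    }))
    row$similarity_mean <- mean(sims, na.rm = TRUE)
    row
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Recognition of occluded cues under relaxed containment
#'
#' Occludes every test cue (defaults: the two settings of the occlusion
#' experiments — the first half of the features, and alternating 4-wide
#' bars, both corrupting half the features with background draws from the
#' rem-split marginal) and evaluates recognition at relaxation levels 0-3.
#' Accepted-cue sets are monotone in relax, so recall never decreases with
#' it; precision tends to decrease.
#'
#' @param cfg a [generator_config()].
#' @param relax_levels failed-column counts to tolerate (default `0:3`).
#' @param occlusions list of settings, each a list with `pattern`,
#'   `fraction` and optionally `mode` (default `"background"`).
#' @param m_bits fixed bit depth (default 5).
#' @param fold partition rotation index.
#' @return A data frame with one metrics row per (occlusion, relax).
#' @export
run_experiment5 <- function(cfg, relax_levels = 0:3,
                            occlusions = list(
                              list(pattern = "prefix", fraction = 0.5),
                              list(pattern = "bars", fraction = 0.5)),
                            m_bits = 5L, fold = 0L) {
  part <- partition_corpus(generate_corpus(cfg), fold = fold, seed = cfg$seed)
  feats <- corpus_features(part)
  test <- which(part$split == "test")
  pool <- feats[part$split == "rem", , drop = FALSE]
  bank <- build_bank(part, m_bits)
  rows <- list()
  for (occ in occlusions) {
    mode <- if (is.null(occ$mode)) "background" else occ$mode
    occluded <- t(vapply(seq_along(test), function(i) {
      occlude(feats[test[i], ], mode = mode, fraction = occ$fraction,
              pattern = occ$pattern, seed = cfg$seed + 500L + i, pool = pool)
    }, numeric(ncol(feats))))
    tag <- sprintf("%s:%s:%.2f", mode, occ$pattern, occ$fraction)
    for (rl in relax_levels) {
      rows[[length(rows) + 1L]] <-
        evaluate_bank(bank, part, "exp5", m_bits, relax = rl, occlusion = tag,
                      test_feats = occluded)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
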