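#' Per-register precision and recall of the accept decision
#'
#' Each register is scored as a binary accept/reject classifier whose
#' positives are the test instances of its own class (or classes, for an
#' overlapped register). Precision is `TP / (TP + FP)`, reported as 1 when
#' the register accepts nothing; recall is `TP / (TP + FN)`.
#'
#' @param accepts logical matrix, one row per test instance and one column
#'   per register, `TRUE` where the register accepts the instance.
#' @param true_labels character vector of instance class labels.
#' @param register_labels labels of the registers (columns), possibly
#'   overlapped (`"0+1"`).
#' @param average `"macro"` (unweighted mean over registers, the default) or
#'   `"micro"` (counts pooled over registers before the ratio).
#' @return A list with `per_register` (data frame of label, tp, fp, fn,
#'   precision, recall) and scalar `precision`, `recall`.
#' @export
per_register_metrics <- function(accepts, true_labels, register_labels,
                                 average = c("macro", "micro")) {
  average <- match.arg(average)
  accepts <- as.matrix(accepts)
  if (nrow(accepts) == 0L) stop("empty test set")
  stopifnot(nrow(accepts) == length(true_labels),
            ncol(accepts) == length(register_labels))
  classes <- register_classes(register_labels)
  rows <- lapply(seq_along(register_labels), function(k) {
    pos <- true_labels %in% classes[[k]]
    acc <- accepts[, k]
    tp <- sum(acc & pos); fp <- sum(acc & !pos); fn <- sum(!acc & pos)
    data.frame(label = register_labels[k], tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
               recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (average == "macro") {
    list(per_register = tab,
         precision = mean(tab$precision),
         recall = mean(tab$recall, na.rm = TRUE))
  } else {
    tp <- sum(tab$tp); fp <- sum(tab$fp); fn <- sum(tab$fn)
    list(per_register = tab,
         precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
         recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
  }
}

#' System-level precision and recall of retrieval decisions
#'
#' One decision per instance: the label of the selected register, or `NA`
#' for a rejection. A decision is correct when the true label belongs to the
#' selected register's class set. Precision is correct / non-rejected
#' (reported as 1 with `all_rejected = TRUE` when everything is rejected);
#' recall is correct / all instances. The two coincide when nothing is
#' rejected.
#'
#' @param decisions character vector of selected register labels, `NA` for
#'   rejected cues.
#' @param true_labels character vector of true class labels.
#' @return A list: `precision`, `recall`, `rejection_rate`, `all_rejected`.
#' @export
system_metrics <- function(decisions, true_labels) {
  stopifnot(length(decisions) == length(true_labels))
  n <- length(decisions)
  decided <- !is.na(decisions)
  correct <- sum(vapply(which(decided), function(i) {
    true_labels[i] %in% register_classes(decisions[i])[[1L]]
  }, logical(1L)))
  list(precision = if (any(decided)) correct / sum(decided) else 1,
       recall = correct / n,
       rejection_rate = 1 - mean(decided),
       all_rejected = !any(decided))
}

#' Similarity between a cue and a retrieved feature vector
#'
#' One minus the mean, over mutually assigned features with a non-degenerate
#' quantizer range, of the absolute difference scaled by that feature's
#' fitted range (capped at 1), so the score lies in `[0, 1]` with 1 for a
#' perfect reproduction.
#'
#' @param cue,retrieved numeric feature vectors (`NA` = missing).
#' @param q the [fit_quantizer()] model supplying per-feature ranges.
#' @return Similarity in `[0, 1]`, or `NA` when no feature is mutually
#'   assigned with a usable range.
#' @export
cue_similarity <- function(cue, retrieved, q) {
  stopifnot(inherits(q, "quantizer_model"),
            length(cue) == q$n_features, length(retrieved) == q$n_features)
  usable <- !is.na(cue) & !is.na(retrieved) & (q$hi > q$lo)
  if (!any(usable)) return(NA_real_)
  ratio <- pmin(abs(cue - retrieved)[usable] / (q$hi - q$lo)[usable], 1)
  1 - mean(ratio)
}

#' Convert a relaxation percentage to a failed-column count
#'
#' @param pct percentage of features allowed to fail.
#' @param n_features number of features (default 64).
#' @return `floor(pct / 100 * n_features)`, an integer count.
#' @export
relax_from_percent <- function(pct, n_features = 64L) {
  as.integer(floor(pct / 100 * n_features))
}

#' Express a relaxation count as a percentage of the features
#'
#' With 64 features, counts 1, 2 and 3 print as 1.6, 3.1 and 4.7.
#'
#' @param relax failed-column count.
#' @param n_features number of features (default 64).
#' @param digits decimal places (default 1).
#' @export
relax_as_percent <- function(relax, n_features = 64L, digits = 1L) {
  round(100 * relax / n_features, digits)
}
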