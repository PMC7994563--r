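#' Create a bank of associative memory registers
#'
#' A register bank is an ordered set of labelled associative registers that
#' share one geometry (`n_features` columns by `2^m_bits` levels) and one
#' quantizer. Labels usually name one class each; a register holding several
#' classes (overlapped representation) is labelled by joining the class names
#' with `"+"`, e.g. `"0+1"`.
#'
#' @param labels character vector of unique register labels.
#' @param quantizer a [fit_quantizer()] model shared by all registers.
#' @param relax bank-level relaxation: tolerated count of feature columns
#'   failing containment before a cue is rejected (default 0).
#' @return An object of class `register_bank`.
#' @export
register_bank <- function(labels, quantizer, relax = 0L) {
  stopifnot(inherits(quantizer, "quantizer_model"))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("register labels must be unique")
  relax <- as.integer(relax)
  stopifnot(relax >= 0L)
  registers <- lapply(labels, function(lb) {
    list(label = lb,
         table = relation(quantizer$n_features, quantizer$n_levels),
         registered_count = 0L)
  })
  names(registers) <- labels
  structure(list(registers = registers, quantizer = quantizer, relax = relax),
            class = "register_bank")
}

#' @export
print.register_bank <- function(x, ...) {
  ent <- vapply(x$registers, function(r) ric_entropy(r$table), numeric(1L))
  cat(sprintf("<register_bank> %d registers (%d x %d), relax = %d\n",
              length(x$registers), x$quantizer$n_features,
              x$quantizer$n_levels, x$relax))
  cat(sprintf("  labels: %s\n", paste(names(x$registers), collapse = " ")))
  cat(sprintf("  entropy: %.3f .. %.3f bits\n", min(ent), max(ent)))
  invisible(x)
}

#' Labels of a bank's registers, in bank order
#' @param bank a [register_bank()].
#' @export
bank_labels <- function(bank) names(bank$registers)

#' Classes covered by a register label
#'
#' Splits an overlapped label such as `"0+1"` into its class identifiers.
#' @param label register label(s).
#' @return A list of character vectors, one per label.
#' @export
register_classes <- function(label) strsplit(as.character(label), "+", fixed = TRUE)

# Accept either a real feature vector or an already-quantized discrete_fn.
as_cue <- function(bank, f) {
  if (inherits(f, "discrete_fn")) {
    if (n_args(f) != bank$quantizer$n_features ||
        n_levels(f) != bank$quantizer$n_levels) {
      stop_mismatch("cue and bank differ")
    }
    f
  } else {
    quantize(f, bank$quantizer)
  }
}

#' Register an instance into one labelled register
#'
#' The memory-write protocol: the cue is quantized, written diagrammatically
#' into the (transient) auxiliary register, and the target register becomes
#' the abstraction of its previous content with it. Only the addressed
#' register is active; the rest of the bank is untouched. Which register to
#' address is the caller's decision (an external attention mechanism).
#'
#' @param bank a [register_bank()].
#' @param f real feature vector (or a [discrete_fn()] already on the bus).
#' @param label label of the target register; must exist in the bank.
#' @return The updated bank.
#' @export
memory_register <- function(bank, f, label) {
  label <- as.character(label)
  if (!label %in% names(bank$registers)) {
    stop(sprintf("unknown register label '%s'", label))
  }
  cue <- as_cue(bank, f)
  lv <- unclass(cue)
  idx <- which(!is.na(lv))
  reg <- bank$registers[[label]]
  if (length(idx)) reg$table$cells[cbind(lv[idx] + 1L, idx)] <- TRUE
  reg$registered_count <- reg$registered_count + 1L
  bank$registers[[label]] <- reg
  bank
}

#' Recognize a cue against every register in the bank
#'
#' All registers are active: each evaluates one containment test of the
#' quantized cue against its table at the bank's relaxation and reports its
#' accept status, failed-column count, and entropy. The system accepts iff
#' at least one register accepts.
#'
#' @param bank a [register_bank()].
#' @param f real feature vector (or [discrete_fn()]) to recognize.
#' @return A `recognition_report`: a data frame with one row per register
#'   (`label`, `accept`, `failed_args`, `entropy`), plus attributes
#'   `system_accept` and `accepting_labels`.
#' @export
memory_recognize <- function(bank, f) {
  cue <- as_cue(bank, f)
  rows <- lapply(bank$registers, function(reg) {
    ct <- containment(cue, reg$table, relax = bank$relax)
    data.frame(label = reg$label, accept = ct$accept,
               failed_args = ct$failed_args,
               entropy = ric_entropy(reg$table),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(report, "system_accept") <- any(report$accept)
  attr(report, "accepting_labels") <- report$label[report$accept]
  class(report) <- c("recognition_report", "data.frame")
  report
}

#' Retrieve an object from the bank given a cue
#'
#' Recognition is run first; if no register accepts, the cue is rejected
#' (a value, not an error). Otherwise the accepting register with minimal
#' entropy is selected (ties broken by bank order), the reduction operation
#' constructs a function from its table centred on the cue, and the result
#' is converted back to real feature values.
#'
#' @param bank a [register_bank()].
#' @param f real feature vector (or [discrete_fn()]) used as the cue.
#' @param policy a [reduction_policy()] governing the constructive selection.
#' @return A `retrieval_result` list: `accepted`, `label`, `features`
#'   (dequantized), `fn` (the retrieved [discrete_fn()]), `entropy` of the
#'   selected register, and the full recognition `report`. On rejection only
#'   `accepted = FALSE` and the report are meaningful.
#' @export
memory_retrieve <- function(bank, f, policy = reduction_policy("identity")) {
  cue <- as_cue(bank, f)
  report <- memory_recognize(bank, cue)
  if (!attr(report, "system_accept")) {
    return(structure(list(accepted = FALSE, label = NA_character_,
                          features = NULL, fn = NULL, entropy = NA_real_,
                          report = report),
                     class = "retrieval_result"))
  }
  acc <- which(report$accept)
  sel <- acc[which.min(report$entropy[acc])]
  label <- report$label[sel]
  out <- reduction(cue, bank$registers[[label]]$table, policy = policy,
                   relax = bank$relax)
  structure(list(accepted = TRUE, label = label,
                 features = dequantize(out, bank$quantizer), fn = out,
                 entropy = report$entropy[sel], report = report),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("<retrieval> accepted by '%s' (e = %.3f bits)\n",
                x$label, x$entropy))
  } else {
    cat("<retrieval> rejected: no register accepts the cue\n")
  }
  invisible(x)
}

#' Persist a register bank to JSON
#'
#' Writes the bank bit-exactly: quantizer ranges at full precision and each
#' register's table as `2^m` rows of `n_features` 0/1 integers, row index 0
#' being level 0. [load_bank()] inverts it exactly.
#'
#' @param bank a [register_bank()].
#' @param path file path to write.
#' @return Invisibly, `path`.
#' @export
save_bank <- function(bank, path) {
  q <- bank$quantizer
  obj <- list(
    version = 1L,
    n_features = q$n_features,
    m_bits = q$m_bits,
    quantizer = list(lo = as.numeric(q$lo), hi = as.numeric(q$hi)),
    relax = bank$relax,
    registers = lapply(unname(bank$registers), function(reg) {
      rows <- lapply(seq_len(q$n_levels), function(v) {
        as.integer(reg$table$cells[v, ])
      })
      list(label = reg$label, registered_count = reg$registered_count,
           rows = rows)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a register bank saved by [save_bank()]
#'
#' Validates geometry while reading; a malformed file is reported with the
#' first offending field (naming the register when its table is wrong).
#'
#' @param path file path to read.
#' @return A [register_bank()].
#' @export
load_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (fld in c("version", "n_features", "m_bits", "quantizer", "relax",
                "registers")) {
    if (is.null(obj[[fld]])) stop(sprintf("bank file: missing field '%s'", fld))
  }
  n_features <- as.integer(obj$n_features)
  m_bits <- as.integer(obj$m_bits)
  n_lv <- 2L^m_bits
  lo <- as.numeric(unlist(obj$quantizer$lo))
  hi <- as.numeric(unlist(obj$quantizer$hi))
  if (length(lo) != n_features || length(hi) != n_features) {
    stop("bank file: quantizer 'lo'/'hi' length differs from n_features")
  }
  if (any(hi < lo)) stop("bank file: quantizer has hi < lo")
  q <- structure(list(n_features = n_features, m_bits = m_bits,
                      n_levels = n_lv, lo = lo, hi = hi),
                 class = "quantizer_model")
  labels <- vapply(obj$registers, function(r) as.character(r$label),
                   character(1L))
  bank <- register_bank(labels, q, relax = as.integer(obj$relax))
  for (r in obj$registers) {
    if (length(r$rows) != n_lv) {
      stop(sprintf("bank file: register '%s' has %d rows, expected %d",
                   r$label, length(r$rows), n_lv))
    }
    cells <- matrix(FALSE, nrow = n_lv, ncol = n_features)
    for (v in seq_len(n_lv)) {
      row <- unlist(r$rows[[v]])
      if (length(row) != n_features) {
        stop(sprintf("bank file: register '%s' row %d has %d entries, expected %d",
                     r$label, v - 1L, length(row), n_features))
      }
      if (!all(row %in% c(0L, 1L))) {
        stop(sprintf("bank file: register '%s' row %d has a non-binary cell",
                     r$label, v - 1L))
      }
      cells[v, ] <- as.logical(as.integer(row))
    }
    bank$registers[[r$label]]$table <- new_relation(cells)
    bank$registers[[r$label]]$registered_count <- as.integer(r$registered_count)
  }
  bank
}
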