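#' Abstraction: cell-wise disjunction of two relations
#'
#' The memory-write primitive. The result relates argument `i` to level `v`
#' whenever either input does; it is commutative, associative and idempotent,
#' with the empty relation as identity, so an associative register is the
#' abstraction of everything ever written into it, independent of order.
#'
#' @param r_f,r_a relations of identical geometry (either may also be a
#'   [discrete_fn()], which is written diagrammatically first).
#' @return A `ric_relation` of the shared geometry.
#' @export
abstraction <- function(r_f, r_a) {
  r_f <- as_relation(r_f)
  r_a <- as_relation(r_a)
  if (!same_geometry(r_f, r_a)) stop_mismatch("abstraction operands differ")
  new_relation(r_f$cells | r_a$cells)
}

as_relation <- function(x) {
  if (inherits(x, "ric_relation")) return(x)
  if (inherits(x, "discrete_fn")) return(function_to_relation(x))
  stop("expected a ric_relation or discrete_fn")
}

#' Containment: the recognition test
#'
#' Tests whether every marked cell of the cue `r_a` is marked in `r_f`
#' (material implication cell by cell, i.e. the subset relation). The test
#' can be relaxed: a cue is still accepted when at most `relax` argument
#' columns contain a mark missing from `r_f`. Unassigned cue arguments
#' impose no constraint.
#'
#' @param r_a the cue, a `ric_relation` or [discrete_fn()].
#' @param r_f the reference relation (register content).
#' @param relax maximum tolerated number of failing argument columns
#'   (default 0: strict containment).
#' @return A list with `accept` (logical) and `failed_args` (count of
#'   argument columns with at least one cue mark absent from `r_f`).
#' @export
containment <- function(r_a, r_f, relax = 0L) {
  stopifnot(inherits(r_f, "ric_relation"), relax >= 0L)
  bump_count("containment")
  if (inherits(r_a, "discrete_fn")) {
    if (!same_geometry(r_a, r_f)) stop_mismatch("cue and relation differ")
    lv <- unclass(r_a)
    idx <- which(!is.na(lv))
    failed <- if (length(idx)) {
      sum(!r_f$cells[cbind(lv[idx] + 1L, idx)])
    } else 0L
  } else {
    r_a <- as_relation(r_a)
    if (!same_geometry(r_a, r_f)) stop_mismatch("cue and relation differ")
    failed <- sum(colSums(r_a$cells & !r_f$cells) > 0L)
  }
  list(accept = failed <= relax, failed_args = as.integer(failed))
}

#' Reduction policy: how retrieval selects among a relation's values
#'
#' `identity` returns the cue's own level when the relation holds it and the
#' nearest held level otherwise; `triangular` samples each argument's level
#' from the relation's marked set with probability proportional to a discrete
#' triangular kernel peaking at the cue's level. The policy object carries its
#' own random stream, seeded once; successive reductions advance it, and no
#' global RNG state is touched.
#'
#' @param mode `"identity"` or `"triangular"`.
#' @param seed integer seed for the policy's private random stream.
#' @return An object of class `reduction_policy`.
#' @export
reduction_policy <- function(mode = c("identity", "triangular"), seed = 1L) {
  mode <- match.arg(mode)
  p <- new.env(parent = emptyenv())
  p$mode <- mode
  p$seed <- as.integer(seed)
  p$state <- with_seed(p$seed, get(".Random.seed", envir = globalenv()))
  class(p) <- "reduction_policy"
  p
}

#' @export
print.reduction_policy <- function(x, ...) {
  cat(sprintf("<reduction_policy> mode=%s seed=%d\n", x$mode, x$seed))
  invisible(x)
}

# Run expr under the policy's private RNG stream, advancing it.
policy_eval <- function(policy, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  assign(".Random.seed", policy$state, envir = genv)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  res <- force(expr)
  policy$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  res
}

#' Reduction: constructive retrieval of a function from a relation
#'
#' Functional application in relational-indeterminate computing. If the cue
#' passes [containment()] (at the given relaxation) the result assigns, for
#' each argument whose column in `r_f` holds at least one level, a level
#' drawn from that marked set: the cue's own level (or the nearest marked
#' one) under the identity policy, or a draw from a triangular kernel
#' centred on the cue under the triangular policy. Arguments with empty
#' columns stay unassigned. A cue that fails containment yields `NULL`
#' (a rejection value, not an error).
#'
#' For an argument the cue leaves unassigned, the kernel is centred at the
#' lower median of the column's marked levels, so both policies behave
#' identically on single-level columns.
#'
#' @param f_a the cue, a [discrete_fn()].
#' @param r_f the relation to reduce against.
#' @param policy a [reduction_policy()].
#' @param relax relaxation forwarded to the containment test.
#' @return A `discrete_fn`, or `NULL` when the cue is rejected.
#' @export
reduction <- function(f_a, r_f, policy = reduction_policy("identity"),
                      relax = 0L) {
  stopifnot(inherits(f_a, "discrete_fn"), inherits(r_f, "ric_relation"),
            inherits(policy, "reduction_policy"))
  if (!same_geometry(f_a, r_f)) stop_mismatch("cue and relation differ")
  if (!containment(f_a, r_f, relax = relax)$accept) return(NULL)
  lv <- unclass(f_a)
  out <- rep(NA_integer_, length(lv))
  supports <- lapply(seq_along(lv), function(i) which(r_f$cells[, i]) - 1L)
  pick <- function(i) {
    s <- supports[[i]]
    if (length(s) == 0L) return(NA_integer_)
    centre <- if (!is.na(lv[i])) lv[i] else s[ceiling(length(s) / 2)]
    if (length(s) == 1L) return(s)
    if (policy$mode == "identity") {
      if (!is.na(lv[i]) && lv[i] %in% s) return(lv[i])
      return(s[which.min(abs(s - centre))])
    }
    d <- abs(s - centre)
    w <- max(d) + 1L - d
    sample(s, 1L, prob = w)
  }
  if (policy$mode == "triangular") {
    out <- policy_eval(policy, vapply(seq_along(lv), pick, integer(1L)))
  } else {
    out <- vapply(seq_along(lv), pick, integer(1L))
  }
  discrete_fn(out, n_levels(r_f))
}

#' Computational entropy of a relation
#'
#' The average indeterminacy of a relation, in bits: the mean over argument
#' columns of `log2` of the number of levels the column holds. Columns with
#' no marked level contribute zero, so (partial) functions have entropy zero.
#' For an associative register this measures how many constituent functions
#' the register covers, and governs the precision/recall trade-off.
#'
#' @param r a `ric_relation` or [discrete_fn()].
#' @return Entropy in bits, a non-negative scalar bounded by
#'   `log2(n_levels)`.
#' @export
ric_entropy <- function(r) {
  r <- as_relation(r)
  mu <- colSums(r$cells)
  mean(ifelse(mu > 0L, log2(mu), 0))
}
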