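#' Boolean incidence relation over arguments and quantized levels
#'
#' A relation maps each of `n_args` arguments (feature tracks, 1-based in R)
#' to any subset of `n_levels` discrete levels (0-based, matching the binary
#' values written on the bus). It is stored densely as a logical matrix with
#' one row per level and one column per argument; cell `(i, v)` is `TRUE` iff
#' argument `i` is related to level `v`. This is the content of an associative
#' memory register.
#'
#' @param n_args number of arguments (columns), a positive integer.
#' @param n_levels number of levels (rows), a positive integer.
#' @param marks optional two-column matrix or data frame of initial marks;
#'   first column the argument index (1-based), second the level (0-based).
#' @return An object of class `ric_relation`.
#' @examples
#' r <- relation(3, 4, marks = cbind(c(1, 2), c(0, 3)))
#' ric_entropy(r)
#' @export
relation <- function(n_args, n_levels, marks = NULL) {
  n_args <- as.integer(n_args)
  n_levels <- as.integer(n_levels)
  stopifnot(length(n_args) == 1L, n_args >= 1L,
            length(n_levels) == 1L, n_levels >= 1L)
  cells <- matrix(FALSE, nrow = n_levels, ncol = n_args)
  if (!is.null(marks)) {
    marks <- as.matrix(marks)
    if (ncol(marks) != 2L) stop("'marks' must have two columns (arg, level)")
    arg <- as.integer(marks[, 1L])
    lev <- as.integer(marks[, 2L])
    if (any(arg < 1L | arg > n_args)) stop("mark argument index out of range")
    if (any(lev < 0L | lev > n_levels - 1L)) stop("mark level out of range")
    cells[cbind(lev + 1L, arg)] <- TRUE
  }
  new_relation(cells)
}

new_relation <- function(cells) {
  stopifnot(is.matrix(cells), is.logical(cells))
  structure(list(cells = cells), class = "ric_relation")
}

#' @export
print.ric_relation <- function(x, ...) {
  cat(sprintf("<ric_relation> %d args x %d levels, %d marked cells, e = %.4f bits\n",
              n_args(x), n_levels(x), sum(x$cells), ric_entropy(x)))
  invisible(x)
}

n_args <- function(x) UseMethod("n_args")
#' @export
n_args.ric_relation <- function(x) ncol(x$cells)
#' @export
n_args.discrete_fn <- function(x) length(unclass(x))

n_levels <- function(x) UseMethod("n_levels")
#' @export
n_levels.ric_relation <- function(x) nrow(x$cells)
#' @export
n_levels.discrete_fn <- function(x) attr(x, "n_levels")

same_geometry <- function(a, b) {
  n_args(a) == n_args(b) && n_levels(a) == n_levels(b)
}

#' Partial discrete function on the bus
#'
#' A (possibly partial) assignment of one level to each argument: the form in
#' which cues and retrieved objects travel on the bus. Levels are 0-based
#' integers in `[0, n_levels - 1]`; `NA` marks an unassigned argument.
#'
#' @param levels integer vector of levels, `NA` for unassigned arguments.
#' @param n_levels number of available levels.
#' @return An object of class `discrete_fn`.
#' @examples
#' f <- discrete_fn(c(1, 0, NA), n_levels = 2)
#' function_to_relation(f)
#' @export
discrete_fn <- function(levels, n_levels) {
  n_levels <- as.integer(n_levels)
  stopifnot(length(n_levels) == 1L, n_levels >= 1L)
  lv <- as.integer(levels)
  bad <- !is.na(lv) & (lv < 0L | lv > n_levels - 1L)
  if (any(bad)) {
    stop(sprintf("level %d out of range [0, %d]", lv[which(bad)[1L]], n_levels - 1L))
  }
  structure(lv, n_levels = n_levels, class = "discrete_fn")
}

#' @export
print.discrete_fn <- function(x, ...) {
  cat(sprintf("<discrete_fn> %d args, %d levels, %d assigned\n",
              n_args(x), n_levels(x), sum(!is.na(unclass(x)))))
  invisible(x)
}

#' Convert a discrete function to its relation (diagrammatic write)
#'
#' Produces the relation with exactly one marked cell per assigned argument,
#' the form in which a function is written into an auxiliary register.
#'
#' @param f a [discrete_fn()].
#' @return A `ric_relation` with at most one mark per column.
#' @export
function_to_relation <- function(f) {
  stopifnot(inherits(f, "discrete_fn"))
  lv <- unclass(f)
  attributes(lv) <- NULL
  cells <- matrix(FALSE, nrow = n_levels(f), ncol = length(lv))
  idx <- which(!is.na(lv))
  if (length(idx)) cells[cbind(lv[idx] + 1L, idx)] <- TRUE
  new_relation(cells)
}

#' Extract the discrete function stored in a functional relation
#'
#' Inverse of [function_to_relation()]; defined only when every column holds
#' at most one mark (the relation is a partial function).
#'
#' @param r a `ric_relation` with at most one mark per column.
#' @return A `discrete_fn`; unmarked columns are unassigned.
#' @export
relation_to_function <- function(r) {
  stopifnot(inherits(r, "ric_relation"))
  mu <- colSums(r$cells)
  if (any(mu > 1L)) {
    stop("relation is not a function: some column holds more than one level")
  }
  lv <- rep(NA_integer_, n_args(r))
  for (i in which(mu == 1L)) lv[i] <- which(r$cells[, i]) - 1L
  discrete_fn(lv, n_levels(r))
}
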