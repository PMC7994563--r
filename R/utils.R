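# Internal operation counters. The recognition protocol is required to cost
# exactly one containment evaluation per register (no iteration); the counter
# makes that property observable in tests.
.eamem_counters <- new.env(parent = emptyenv())
.eamem_counters$containment <- 0L

op_count <- function(name = "containment") {
  get(name, envir = .eamem_counters)
}

op_count_reset <- function() {
  assign("containment", 0L, envir = .eamem_counters)
  invisible(NULL)
}

bump_count <- function(name) {
  assign(name, get(name, envir = .eamem_counters) + 1L, envir = .eamem_counters)
  invisible(NULL)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

stop_mismatch <- function(what) {
  stop(sprintf("geometry mismatch: %s", what), call. = FALSE)
}
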