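#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange desc mutate filter select left_join group_by summarise ungroup row_number bind_rows n
#' @importFrom stats rbinom rnorm runif rbeta coef lm pf var t.test
#' @importFrom utils head packageVersion read.delim write.table
NULL

# Derive independent child seeds (< 2^31) from one user seed.  Each named
# stream gets its own reproducible sub-seed so that, e.g., the collapsing
# sequence is invariant to the number of CV folds.
derive_seeds <- function(seed, streams) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max - 1L, length(streams))
  names(out) <- streams
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate expr with the RNG temporarily seeded; restores the caller's state.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
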