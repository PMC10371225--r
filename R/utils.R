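# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed without disturbing the caller
#'
#' All stochastic operations in the package funnel through this helper so that
#' a `seed` argument gives bit-reproducible output while leaving the global
#' RNG stream untouched.
#' @keywords internal
#' @noRd
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed derivation; stays below 2^31 - 1 (exact in doubles).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + 97 * as.double(index)) %% 2147483647)
}

spearman <- function(x, y) {
  stats::cor(x, y, method = "spearman", use = "everything")
}

# Two-sided surrogate p-value with the +1 correction.
surrogate_p <- function(observed, null_values) {
  null_values <- null_values[is.finite(null_values)]
  (1 + sum(abs(null_values) >= abs(observed))) / (length(null_values) + 1)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_square_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_invalid("%s must be a square matrix", what)
  }
  if (max(abs(m - t(m))) > tol) {
    stop_invalid("%s must be symmetric (max asymmetry %.3g)", what,
                 max(abs(m - t(m))))
  }
  invisible(TRUE)
}

# Canonical names of the 19 NTRM density maps in the reference PET panel.
ntrm_names <- function() {
  c("5-HTT", "5-HT1a", "5-HT1b", "5-HT2a", "5-HT4", "5-HT6",
    "D1", "D2", "DAT", "GABAa", "NMDA", "M1", "VAChT",
    "A4B2", "NAT", "H3", "MU", "CB1", "mGluR5")
}
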