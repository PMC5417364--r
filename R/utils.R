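`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_is <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_is <- function(...) warning(sprintf(...), call. = FALSE)

# All stochastic code in the package funnels through this: the caller's RNG
# state is untouched and a NULL seed means "use current stream" (needed when
# a parent generator has already seeded).
#' @noRd
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

#' @noRd
assert_matrix_samples <- function(m, samples, what = "matrix") {
  missing <- setdiff(samples, colnames(m))
  if (length(missing))
    stop_is("%s is missing sample columns: %s", what,
            paste(missing, collapse = ", "))
  invisible(TRUE)
}

# Stable interval-overlap length between one interval and a set of intervals.
#' @noRd
overlap_bp <- function(s, e, starts, ends) {
  sum(pmax(0L, pmin(e, ends) - pmax(s, starts)))
}
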