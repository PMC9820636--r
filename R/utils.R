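#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a counter
#'
#' Child seeds are a pure function of `(master, index)`, so the i-th item of
#' a generated dataset does not depend on how many items precede it.
#' Kept below 2^31 so the result is always a valid R integer seed.
#' @noRd
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 104729) %%
               2147483629)
}

#' Stop with a parameter error naming the offending field
#' @noRd
param_error <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                              lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    param_error(field, "must be a finite numeric scalar")
  if (x < lower || (lower_open && x == lower))
    param_error(field, sprintf("must be %s %s", if (lower_open) ">" else ">=", lower))
  if (x > upper || (upper_open && x == upper))
    param_error(field, sprintf("must be %s %s", if (upper_open) "<" else "<=", upper))
  invisible(x)
}
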