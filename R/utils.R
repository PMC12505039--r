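# Internal numerical and validation helpers.

#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (a == b to machine precision).
#' @keywords internal
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

VALID_ALLELES <- c("A", "C", "G", "T")

complement_allele <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

is_palindromic <- function(ea, oa) {
  ea == unname(complement_allele(oa))
}
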