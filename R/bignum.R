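# Minimal arbitrary-precision non-negative integers, base 1e4, little-endian
# digit vectors. Only addition and multiplication are needed (for the
# delimitation-model count, which overflows doubles beyond ~60 tips).

BIG_BASE <- 10000L

big_from_int <- function(n) {
  stopifnot(n >= 0)
  d <- integer(0)
  n <- as.integer(n)
  repeat {
    d <- c(d, n %% BIG_BASE)
    n <- n %/% BIG_BASE
    if (n == 0L) break
  }
  structure(d, class = "gmyc_bigint")
}

big_norm <- function(d) {
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  while (carry > 0) {
    d <- c(d, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  structure(as.numeric(d), class = "gmyc_bigint")
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(unclass(a), numeric(n - length(a))) +
           c(unclass(b), numeric(n - length(b))))
}

big_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  # accumulated digits stay below length(b) * 1e8, far under 2^53 for any
  # tree size this package meets
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    idx <- seq_along(b) + i - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  big_norm(out)
}

#' @export
format.gmyc_bigint <- function(x, ...) {
  d <- rev(unclass(x))
  paste0(d[1], paste(sprintf("%04d", d[-1]), collapse = ""))
}

#' @export
print.gmyc_bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.numeric.gmyc_bigint <- function(x, ...) {
  sum(unclass(x) * BIG_BASE^(seq_along(x) - 1))
}
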