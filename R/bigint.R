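# Exact natural-number arithmetic for reference-set cardinalities.
#
# Counts such as 630^7 or 49!/(7! 14!^3) exceed the 2^53 integer range of
# doubles, so sizes are carried as exact big naturals: little-endian digit
# vectors in base 1e6 (digit products stay well inside the exactly
# representable double range).  Only multiplication is ever needed:
# factorials and multinomial coefficients are assembled from their prime
# factorizations (Legendre's formula), which avoids big-integer division.

BI_BASE <- 1e6

bigNatural <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1, x >= 0, x == floor(x), x < 2^53)
  digits <- numeric(0)
  repeat {
    digits <- c(digits, x %% BI_BASE)
    x <- x %/% BI_BASE
    if (x == 0) break
  }
  structure(list(digits = digits), class = "bigNatural")
}

bi_norm <- function(d) {
  # propagate carries, strip leading zeros
  i <- 1
  while (i <= length(d)) {
    if (d[i] >= BI_BASE) {
      carry <- d[i] %/% BI_BASE
      d[i] <- d[i] %% BI_BASE
      if (i == length(d)) d <- c(d, 0)
      d[i + 1] <- d[i + 1] + carry
    }
    i <- i + 1
  }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

bi_mul <- function(a, b) {
  da <- a$digits; db <- b$digits
  res <- numeric(length(da) + length(db))
  for (i in seq_along(da)) {
    if (da[i] == 0) next
    idx <- seq_along(db) + i - 1L
    res[idx] <- res[idx] + da[i] * db
    # renormalize eagerly so partial sums stay < 2^53
    res <- bi_norm(res)
    pad <- length(da) + length(db) - length(res)
    if (pad > 0) res <- c(res, numeric(pad))
  }
  structure(list(digits = bi_norm(res)), class = "bigNatural")
}

bi_pow <- function(a, e) {
  stopifnot(e >= 0, e == floor(e))
  out <- bigNatural(1)
  base <- a
  while (e > 0) {
    if (e %% 2 == 1) out <- bi_mul(out, base)
    base <- bi_mul(base, base)
    e <- e %/% 2
  }
  out
}

# exponent of prime p in n! (Legendre)
legendre_exponent <- function(n, p) {
  e <- 0; q <- p
  while (q <= n) { e <- e + n %/% q; q <- q * p }
  e
}

primes_upto <- function(n) {
  if (n < 2) return(integer(0))
  sieve <- rep(TRUE, n)
  sieve[1] <- FALSE
  p <- 2
  while (p * p <= n) {
    if (sieve[p]) sieve[seq(p * p, n, by = p)] <- FALSE
    p <- p + 1
  }
  which(sieve)
}

# n! / (n1! n2! ... nk!) exactly, via prime factorization
bi_multinomial <- function(n, parts) {
  stopifnot(sum(parts) == n)
  out <- bigNatural(1)
  for (p in primes_upto(max(n, 2))) {
    e <- legendre_exponent(n, p) - sum(vapply(parts, legendre_exponent,
                                              numeric(1), p = p))
    if (e > 0) out <- bi_mul(out, bi_pow(bigNatural(p), e))
  }
  out
}

#' @export
format.bigNatural <- function(x, ...) {
  d <- rev(x$digits)
  paste0(format(d[1], scientific = FALSE),
         paste(sprintf("%06.0f", d[-1]), collapse = ""))
}

#' @export
print.bigNatural <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.double.bigNatural <- function(x, ...) {
  sum(x$digits * BI_BASE^(seq_along(x$digits) - 1))
}

#' @export
as.character.bigNatural <- function(x, ...) format(x)

#' @export
"==.bigNatural" <- function(e1, e2) {
  identical(bi_norm(e1$digits), bi_norm(e2$digits))
}
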