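# Minimal exact non-negative decimal big integer, used so that theoretical
# library diversities (up to ~1e22, beyond exact double range) are computed
# without rounding. Stored as an integer vector of decimal digits, most
# significant first.

big_from_int <- function(n) {
  stopifnot(length(n) == 1L, n >= 0, n == floor(n), n < 2^53)
  if (n == 0) return(structure(0L, class = "sy_bigint"))
  d <- integer(0)
  while (n > 0) {
    d <- c(as.integer(n %% 10), d)
    n <- floor(n / 10)
  }
  structure(d, class = "sy_bigint")
}

# multiply by a small integer factor (factor * 9 + carry must stay < 2^31)
big_mul_small <- function(d, k) {
  stopifnot(inherits(d, "sy_bigint"), k >= 0, k == floor(k), k < 1e8)
  if (k == 0 || (length(d) == 1L && d[1] == 0L)) return(big_from_int(0))
  x <- rev(as.integer(unclass(d))) * k
  carry <- 0
  out <- integer(0)
  for (i in seq_along(x)) {
    v <- x[i] + carry
    out <- c(out, as.integer(v %% 10))
    carry <- floor(v / 10)
  }
  while (carry > 0) {
    out <- c(out, as.integer(carry %% 10))
    carry <- floor(carry / 10)
  }
  structure(rev(out), class = "sy_bigint")
}

big_prod <- function(factors) {
  Reduce(big_mul_small, factors, big_from_int(1))
}

#' @export
as.character.sy_bigint <- function(x, ...) paste(unclass(x), collapse = "")

#' @export
as.double.sy_bigint <- function(x, ...) as.numeric(as.character(x))

# round to `digits` significant figures, returned as mantissa/exponent
big_signif <- function(x, digits = 2) {
  stopifnot(inherits(x, "sy_bigint"))
  d <- unclass(x)
  expo <- length(d) - 1L
  if (expo == 0L && d[1] == 0L) return(list(mantissa = 0, exponent = 0))
  k <- min(length(d), digits + 6L)
  mant <- as.numeric(paste0(d[1], ".", paste(d[seq_len(k)][-1], collapse = "")))
  mant <- signif(mant, digits)
  if (mant >= 10) {
    mant <- mant / 10
    expo <- expo + 1L
  }
  list(mantissa = mant, exponent = expo)
}

# numeric value of x rounded to `digits` significant figures (e.g. 8.3e17),
# parsed from its decimal representation so it equals the literal a reader
# would type (mantissa * 10^exponent can differ in the last ulp)
big_signif_num <- function(x, digits = 2) {
  s <- big_signif(x, digits)
  as.numeric(sprintf("%.*ge%d", digits, s$mantissa, s$exponent))
}

#' @export
format.sy_bigint <- function(x, scientific = TRUE, digits = 2, ...) {
  if (!scientific) return(as.character(x))
  s <- big_signif(x, digits)
  sprintf("%s x 10^%d", format(s$mantissa), s$exponent)
}

#' @export
print.sy_bigint <- function(x, ...) {
  cat("<exact integer>", as.character(x), "(~", format(x), ")\n")
  invisible(x)
}
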