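# Arithmetic over GF(2^8) with the standard primitive polynomial 0x11D
# and generator alpha = 2; the substrate for the Reed-Solomon reference
# codecs.  Elements are integers 0..255; all operations are vectorized
# through exp/log tables.

gf_tables <- local({
  tabs <- NULL
  function() {
    if (is.null(tabs)) {
      exp <- integer(255)
      log <- integer(256)
      x <- 1L
      for (i in 0:254) {
        exp[i + 1] <- x
        log[x + 1] <- i
        x <- bitwShiftL(x, 1)
        if (x >= 256L) x <- bitwXor(x, 285L)  # 0x11D
      }
      tabs <<- list(exp = exp, log = log)
    }
    tabs
  }
})

#' GF(256) field operations
#'
#' Addition (= subtraction) is XOR; multiplication, division and powers go
#' through log/antilog tables for the primitive polynomial `0x11D`.
#' All operations are vectorized and recycle their arguments.
#'
#' @param x,y Integer vectors with elements in `[0, 255]`.
#' @param n Integer exponent(s).
#' @return Integer vector of field elements.
#' @export
#' @examples
#' gf_mul(7, gf_div(1, 7))  # 1
gf_add <- function(x, y) bitwXor(as.integer(x), as.integer(y))

#' @rdname gf_add
#' @export
gf_mul <- function(x, y) {
  t <- gf_tables()
  x <- as.integer(x); y <- as.integer(y)
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(integer(0))
  if (nx != ny) {
    n <- max(nx, ny)
    x <- rep_len(x, n); y <- rep_len(y, n)
  }
  out <- integer(length(x))
  nz <- x != 0L & y != 0L
  out[nz] <- t$exp[(t$log[x[nz] + 1L] + t$log[y[nz] + 1L]) %% 255L + 1L]
  out
}

#' @rdname gf_add
#' @export
gf_div <- function(x, y) {
  t <- gf_tables()
  x <- as.integer(x); y <- as.integer(y)
  if (any(y == 0L)) stop("division by zero in GF(256)")
  if (length(x) == 0L || length(y) == 0L) return(integer(0))
  out <- integer(max(length(x), length(y)))
  x <- rep_len(x, length(out)); y <- rep_len(y, length(out))
  nz <- x != 0L
  out[nz] <- t$exp[(t$log[x[nz] + 1L] - t$log[y[nz] + 1L] + 255L) %% 255L + 1L]
  out
}

#' @rdname gf_add
#' @export
gf_pow <- function(x, n) {
  t <- gf_tables()
  x <- as.integer(x); n <- as.integer(n)
  if (length(x) == 0L || length(n) == 0L) return(integer(0))
  out <- integer(max(length(x), length(n)))
  x <- rep_len(x, length(out)); n <- rep_len(n, length(out))
  zero <- x == 0L
  out[!zero] <- t$exp[(t$log[x[!zero] + 1L] * n[!zero]) %% 255L + 1L]
  out[zero] <- ifelse(n[zero] == 0L, 1L, 0L)
  out
}

#' @rdname gf_add
#' @export
gf_inv <- function(x) gf_div(1L, x)

# -- polynomials: integer vectors, highest-degree coefficient first --------

gf_poly_scale <- function(p, x) gf_mul(p, x)

gf_poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  r <- integer(n)
  r[(n - length(p) + 1L):n] <- p
  r[(n - length(q) + 1L):n] <- bitwXor(r[(n - length(q) + 1L):n],
                                       as.integer(q))
  r
}

gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] != 0L) {
      idx <- i:(i + length(q) - 1L)
      r[idx] <- bitwXor(r[idx], gf_mul(p[i], q))
    }
  }
  r
}

#' Evaluate a GF(256) polynomial
#'
#' Horner evaluation of a polynomial with highest-degree coefficient first,
#' vectorized over evaluation points.
#'
#' @param p Integer vector of coefficients (highest degree first).
#' @param x Integer vector of field elements.
#' @return Integer vector `p(x)`.
#' @export
gf_poly_eval <- function(p, x) {
  y <- rep.int(as.integer(p[1L]), length(x))
  for (i in seq_along(p)[-1L]) {
    y <- bitwXor(gf_mul(y, x), as.integer(p[i]))
  }
  y
}

#' Interpolate a GF(256) polynomial through given points
#'
#' Lagrange interpolation: returns the unique polynomial of degree
#' `< length(xs)` through `(xs, ys)`.
#'
#' @param xs,ys Integer vectors of distinct field elements and values.
#' @return Integer coefficient vector (highest degree first).
#' @export
gf_poly_interp <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), !anyDuplicated(xs))
  n <- length(xs)
  acc <- integer(1)  # zero polynomial
  for (i in seq_len(n)) {
    li <- 1L
    denom <- 1L
    for (j in seq_len(n)[-i]) {
      li <- gf_poly_mul(li, c(1L, as.integer(xs[j])))
      denom <- gf_mul(denom, gf_add(xs[i], xs[j]))
    }
    acc <- gf_poly_add(acc, gf_poly_scale(li, gf_div(gf_mul(ys[i], 1L), denom)))
  }
  # drop leading zeros
  nz <- which(acc != 0L)
  if (length(nz) == 0L) return(0L)
  acc[nz[1L]:length(acc)]
}
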