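# Systematic Reed-Solomon block codes over GF(256), with
# errors-and-erasures decoding (Berlekamp-Massey on Forney syndromes,
# Chien search, Forney magnitudes).  Codewords are integer vectors of
# length <= 255: message symbols followed by `nsym` parity symbols.
# Shortened codes (length < 255) work transparently.

rs_generator_poly <- function(nsym) {
  g <- 1L
  for (i in 0:(nsym - 1L)) {
    g <- gf_poly_mul(g, c(1L, gf_pow(2L, i)))
  }
  g
}

#' Encode a Reed-Solomon block
#'
#' Appends `nsym` parity symbols to `msg` (systematic encoding, generator
#' `alpha = 2`, primitive polynomial `0x11D`).  The codeword corrects up
#' to `floor(nsym / 2)` symbol errors, or any mix with
#' `2 * errors + erasures <= nsym`.
#'
#' @param msg Integer vector of message symbols in `[0, 255]`,
#'   `length(msg) + nsym <= 255`.
#' @param nsym Number of parity symbols.
#' @return Integer codeword `c(msg, parity)`.
#' @export
#' @examples
#' cw <- rs_encode_block(c(1, 2, 3, 4), 3)
#' rs_decode_block(cw, 3)$msg
rs_encode_block <- function(msg, nsym) {
  msg <- as.integer(msg)
  stopifnot(all(msg >= 0L & msg <= 255L), nsym >= 1L,
            length(msg) + nsym <= 255L)
  g <- rs_generator_poly(nsym)
  # polynomial division of msg * x^nsym by g; remainder = parity
  rem <- c(msg, integer(nsym))
  for (i in seq_along(msg)) {
    coef <- rem[i]
    if (coef != 0L) {
      idx <- i + seq_along(g) - 1L
      rem[idx] <- bitwXor(rem[idx], gf_mul(coef, g))
    }
  }
  c(msg, rem[(length(msg) + 1L):(length(msg) + nsym)])
}

rs_syndromes <- function(cw, nsym) {
  vapply(0:(nsym - 1L),
         function(j) gf_poly_eval(cw, gf_pow(2L, j)),
         integer(1))
}

# syndromes for many codewords at once: B is an n x C byte matrix,
# result is an nsym x C matrix (column all-zero <=> clean codeword)
batch_syndromes <- function(B, nsym) {
  n <- nrow(B)
  out <- matrix(0L, nrow = nsym, ncol = ncol(B))
  for (j in seq_len(nsym) - 1L) {
    a <- gf_pow(2L, j)
    y <- B[1L, ]
    for (row in seq_len(n)[-1L]) {
      y <- bitwXor(gf_mul(y, a), B[row, ])
    }
    out[j + 1L, ] <- y
  }
  out
}

#' Decode a Reed-Solomon block with errors and erasures
#'
#' @param received Integer codeword (message + parity), possibly corrupted;
#'   erased positions may hold any value.
#' @param nsym Number of parity symbols used at encoding.
#' @param erase_pos Integer vector of known-erased positions (1-based
#'   indices into `received`).
#' @param synd Optional precomputed syndrome vector (performance).
#' @return A list with `ok` (logical), `msg` (corrected message symbols or
#'   `NULL`), `codeword`, `n_corrected` (number of corrected symbol errors,
#'   not counting erasures), and `n_erased`.
#' @export
rs_decode_block <- function(received, nsym, erase_pos = integer(0),
                            synd = NULL) {
  received <- as.integer(received)
  n <- length(received)
  k <- n - nsym
  fail <- function() list(ok = FALSE, msg = NULL, codeword = NULL,
                          n_corrected = NA_integer_,
                          n_erased = length(erase_pos))
  if (length(erase_pos) > nsym) return(fail())
  if (is.null(synd)) synd <- rs_syndromes(received, nsym)
  if (all(synd == 0L)) {
    return(list(ok = TRUE, msg = received[seq_len(k)], codeword = received,
                n_corrected = 0L, n_erased = length(erase_pos)))
  }
  # erasure locator from positions (locators X_i = alpha^(n - pos))
  erase_loc <- 1L
  erase_x <- gf_pow(2L, n - as.integer(erase_pos))
  for (x in erase_x) erase_loc <- gf_poly_mul(erase_loc, c(x, 1L))
  # Forney syndromes: remove erasure contribution
  fsynd <- synd
  for (x in erase_x) {
    fsynd <- c(bitwXor(gf_mul(fsynd[-length(fsynd)], x), fsynd[-1L]), 0L)
    fsynd <- fsynd[seq_len(nsym)]
  }
  fsynd_use <- fsynd[seq_len(nsym - length(erase_pos))]
  # Berlekamp-Massey for the error locator on the Forney syndromes
  err_loc <- bm_error_locator(fsynd_use)
  n_err <- length(err_loc) - 1L
  if (2L * n_err + length(erase_pos) > nsym) return(fail())
  # combined errata locator (descending coefficients) and root search
  errata_loc <- gf_poly_mul(rev(err_loc), erase_loc)
  deg <- length(errata_loc) - 1L
  pos_all <- seq_len(n)
  xs <- gf_pow(2L, n - pos_all)
  vals <- gf_poly_eval(errata_loc, gf_inv_vec(xs))
  roots_pos <- pos_all[vals == 0L]
  if (length(roots_pos) != deg) return(fail())
  corrected <- rs_correct_errata(received, synd, roots_pos, n)
  if (is.null(corrected)) return(fail())
  if (any(rs_syndromes(corrected, nsym) != 0L)) return(fail())
  list(ok = TRUE, msg = corrected[seq_len(k)], codeword = corrected,
       n_corrected = length(setdiff(roots_pos, as.integer(erase_pos))),
       n_erased = length(erase_pos))
}

gf_inv_vec <- function(x) {
  out <- integer(length(x))
  nz <- x != 0L
  out[nz] <- gf_div(1L, x[nz])
  out
}

# Berlekamp-Massey: minimal LFSR (error locator, ascending coefficient
# order c(1, l1, l2, ...)) generating the syndrome sequence.  Scalar
# field arithmetic is inlined through the log/antilog tables — this is
# the innermost loop of bulk decoding.
bm_error_locator <- function(synd) {
  t <- gf_tables(); texp <- t$exp; tlog <- t$log
  C <- 1L; B <- 1L
  L <- 0L; m <- 1L; b <- 1L
  n <- length(synd)
  for (i in seq_len(n)) {
    d <- synd[i]
    if (L > 0) {
      for (j in seq_len(min(L, length(C) - 1L))) {
        cj <- C[j + 1L]; sj <- synd[i - j]
        if (cj != 0L && sj != 0L) {
          d <- bitwXor(d, texp[(tlog[cj + 1L] + tlog[sj + 1L]) %% 255L + 1L])
        }
      }
    }
    if (d == 0L) {
      m <- m + 1L
    } else {
      coef_log <- (tlog[d + 1L] - tlog[b + 1L] + 255L) %% 255L
      Bx <- c(integer(m), B)          # B * x^m, ascending order
      scaled <- integer(length(Bx))
      nzb <- Bx != 0L
      scaled[nzb] <- texp[(tlog[Bx[nzb] + 1L] + coef_log) %% 255L + 1L]
      if (2L * L <= i - 1L) {
        Told <- C
        C <- gf_poly_add_asc(C, scaled)
        L <- i - L
        B <- Told
        b <- d
        m <- 1L
      } else {
        C <- gf_poly_add_asc(C, scaled)
        m <- m + 1L
      }
    }
  }
  C[seq_len(L + 1L)]
}

gf_poly_add_asc <- function(p, q) {
  n <- max(length(p), length(q))
  r <- integer(n)
  r[seq_along(p)] <- p
  r[seq_along(q)] <- bitwXor(r[seq_along(q)], as.integer(q))
  r
}

# Forney algorithm: compute errata magnitudes at the given positions and
# return the corrected codeword (NULL on a degenerate locator).
rs_correct_errata <- function(received, synd, pos, n) {
  xs <- gf_pow(2L, n - as.integer(pos))   # locators X_i
  q <- length(pos)
  # errata locator Lambda(x) = prod(1 + X_i x), descending coefficients
  loc <- 1L
  for (x in xs) loc <- gf_poly_mul(loc, c(x, 1L))
  # errata evaluator Omega(x) = [x S(x) Lambda(x)] mod x^(q+1)
  synd_shifted <- c(rev(as.integer(synd)), 0L)  # x * S(x), descending
  prod <- gf_poly_mul(synd_shifted, loc)
  omega <- prod[(length(prod) - q):length(prod)]
  out <- received
  for (i in seq_len(q)) {
    xi <- xs[i]
    xi_inv <- gf_div(1L, xi)
    denom <- 1L
    for (j in seq_len(q)[-i]) {
      denom <- gf_mul(denom, bitwXor(1L, gf_mul(xi_inv, xs[j])))
    }
    if (denom == 0L) return(NULL)
    mag <- gf_div(gf_mul(xi, gf_poly_eval(omega, xi_inv)), denom)
    out[pos[i]] <- bitwXor(out[pos[i]], mag)
  }
  out
}
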