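# Single-error decoders.  With designed distance 3 (t = 1) the
# Berlekamp-Massey (field) and Modified Berlekamp-Massey (ring) algorithms
# reduce to closed-form syndrome decoding: the error locator has degree at
# most one, so position and magnitude follow directly from (s1, s2).
#
# Positions in a DecodeOutcome are 1-based indices into the symbol vector;
# position i carries the coefficient of x^(n-i), so an error term e*x^p
# sits at position i = n - p.

.decode_outcome <- function(status, position = NA_integer_,
                            magnitude = NA_integer_, corrected = NULL) {
  structure(list(status = status, position = position,
                 magnitude = magnitude, corrected_vector = corrected,
                 ambiguous = FALSE),
            class = "sga_decode")
}

#' @export
print.sga_decode <- function(x, ...) {
  cat("decode outcome: ", x$status, sep = "")
  if (x$status == "corrected")
    cat(" (position ", x$position, ", magnitude ", x$magnitude, ")", sep = "")
  if (isTRUE(x$ambiguous)) cat(" [ambiguous]")
  cat("\n")
  invisible(x)
}

#' Decode a single symbol error
#'
#' Syndrome decoding at t = 1.  Zero syndromes mean the vector is a
#' codeword.  Field case: with \eqn{s_1, s_2 \neq 0}, the error degree j
#' satisfies \eqn{\beta^j = s_2/s_1} and the magnitude is
#' \eqn{e = s_1^2/s_2}, accepted only when e is a GF(4) symbol.  Ring
#' case: if \eqn{s_1} is a unit, j is recovered from the discrete log of
#' the mod-2 images (\eqn{j = \log \bar s_2 - \log \bar s_1}) and the
#' magnitude \eqn{e \in \{1,3\}} is confirmed against both syndromes; if
#' \eqn{s_1 \in 2\,GR(4,m)}, halving gives the mod-2 image of
#' \eqn{\xi^j} directly and the magnitude is \eqn{e = 2}, confirmed by
#' \eqn{s_2 = 2\xi^{2j}}.  Inconsistent syndromes (the vector is farther
#' than Hamming distance 1 from every codeword) yield status
#' \code{"failure"}.
#'
#' @param r integer symbol vector of length n.
#' @param code an \code{sga_code}.
#' @return an \code{sga_decode}: list with \code{status}
#'   (\code{"no_error"}, \code{"corrected"} or \code{"failure"}),
#'   \code{position} (1-based symbol position), \code{magnitude} (the
#'   error value e with input = codeword + e at that position) and
#'   \code{corrected_vector}.
#' @export
decode_single_error <- function(r, code) {
  stopifnot(inherits(code, "sga_code"))
  r <- .check_symbols(r, code)
  n <- code$n
  s <- .syndromes_raw(r, code)
  if (code$kind == "field") {
    s1 <- s$s1; s2 <- s$s2
    if (s1 == 0L && s2 == 0L)
      return(.decode_outcome("no_error", corrected = r))
    if (s1 == 0L || s2 == 0L) return(.decode_outcome("failure"))
    ctx <- code$ctx
    l1 <- ctx$log[s1 + 1L]; l2 <- ctx$log[s2 + 1L]
    j <- (l2 - l1) %% n
    e <- ctx$pow[((2L * l1 - l2) %% n) + 1L]       # s1^2 / s2
    if (e > 3L) return(.decode_outcome("failure")) # magnitude not a symbol
    pos <- n - j
    corrected <- r
    corrected[pos] <- bitwXor(corrected[pos], e)
    .decode_outcome("corrected", pos, e, corrected)
  } else {
    s1 <- s$s1; s2 <- s$s2
    z1 <- all(s1 == 0L); z2 <- all(s2 == 0L)
    if (z1 && z2) return(.decode_outcome("no_error", corrected = r))
    if (z1 || z2) return(.decode_outcome("failure"))
    ctx <- code$ctx
    if (any(s1 %% 2L == 1L)) {                     # unit branch, e in {1,3}
      if (all(s2 %% 2L == 0L)) return(.decode_outcome("failure"))
      j1 <- ctx$gf2_log[.gr_pack2(s1 %% 2L) + 1L]
      j2 <- ctx$gf2_log[.gr_pack2(s2 %% 2L) + 1L]
      j <- (j2 - j1) %% n
      for (e in c(1L, 3L)) {
        ok1 <- all(s1 == (e * ctx$xi_pow[j + 1L, ]) %% 4L)
        ok2 <- all(s2 == (e * ctx$xi_pow[((2L * j) %% n) + 1L, ]) %% 4L)
        if (ok1 && ok2) {
          pos <- n - j
          corrected <- r
          corrected[pos] <- (corrected[pos] - e) %% 4L
          return(.decode_outcome("corrected", pos, e, corrected))
        }
      }
      .decode_outcome("failure")
    } else {                                       # zero-divisor branch, e = 2
      half <- (s1 %/% 2L) %% 2L
      j <- ctx$gf2_log[.gr_pack2(half) + 1L]
      if (is.na(j)) return(.decode_outcome("failure"))
      ok1 <- all(s1 == (2L * ctx$xi_pow[j + 1L, ]) %% 4L)
      ok2 <- all(s2 == (2L * ctx$xi_pow[((2L * j) %% n) + 1L, ]) %% 4L)
      if (!ok1 || !ok2) return(.decode_outcome("failure"))
      pos <- n - j
      corrected <- r
      corrected[pos] <- (corrected[pos] - 2L) %% 4L
      .decode_outcome("corrected", pos, 2L, corrected)
    }
  }
}

# remainder of x^p mod g for p = 0..n-1, by position: row i corresponds to
# symbol position i (degree n-i).  Rows are padded to deg(g) entries.
.remainder_table <- function(code) {
  cache <- code$cache
  if (!is.null(cache$remtab)) return(cache$remtab)
  n <- code$n
  dom <- if (code$kind == "ring") "Z4" else "GF4"
  g <- code$generator$coef
  dg <- length(g) - 1L
  tail <- g[1:dg]
  bydeg <- matrix(0L, nrow = n, ncol = dg)
  rem <- c(1L, integer(dg - 1L))                 # remainder of x^0
  bydeg[1L, ] <- rem
  for (p in 1:(n - 1L)) {                        # x^(p) = x * x^(p-1) mod g
    c <- rem[dg]
    rem <- c(0L, rem[-dg])
    if (c != 0L) {
      red <- if (dom == "Z4") (4L - .coef_mul(c, tail, dom)) %% 4L
             else .coef_mul(c, tail, dom)        # char 2: -t = t
      rem <- .coef_add(rem, red, dom)
    }
    bydeg[p + 1L, ] <- rem
  }
  bypos <- bydeg[(n - seq_len(n)) + 1L, , drop = FALSE]
  cache$remtab <- bypos
  bypos
}

#' Brute-force identification oracle
#'
#' Independent of the syndrome decoder: membership of the input and of all
#' 3n single-symbol modifications is decided through divisibility by the
#' generator polynomial, using the linearity of the division remainder
#' over a precomputed table of remainders of \eqn{x^p \bmod g(x)}.
#' Returns the same contract as \code{\link{decode_single_error}}; when
#' several distance-1 codewords exist the lexicographically smallest
#' (position, magnitude) is returned and \code{ambiguous} is set (this
#' cannot happen within the decoding radius of a distance-3 code).
#'
#' @inheritParams decode_single_error
#' @return an \code{sga_decode}.
#' @export
brute_force_identify <- function(r, code) {
  stopifnot(inherits(code, "sga_code"))
  r <- .check_symbols(r, code)
  n <- code$n
  ring <- code$kind == "ring"
  dom <- if (ring) "Z4" else "GF4"
  remtab <- .remainder_table(code)
  dg <- ncol(remtab)
  rem0 <- .poly_remainder(r, code)
  rem0 <- c(rem0, integer(dg - length(rem0)))
  if (all(rem0 == 0L)) return(.decode_outcome("no_error", corrected = r))
  hits <- NULL                                   # rows: position, magnitude e
  rem0m <- matrix(rem0, nrow = n, ncol = dg, byrow = TRUE)
  for (d in 1:3) {                               # modification delta
    cand <- if (ring) (rem0m + d * remtab) %% 4L
            else matrix(bitwXor(rem0m, gf4_mul(rep(d, length(remtab)), remtab)),
                        nrow = n)
    pos <- which(rowSums(cand) == 0L)
    if (length(pos)) {
      # new symbol s = r[pos] + d (ring) or r[pos] xor d (field);
      # the error magnitude is e with r = codeword + e, i.e. e = -d / d
      e <- if (ring) (4L - d) %% 4L else d
      hits <- rbind(hits, cbind(pos, e, d))
    }
  }
  if (is.null(hits)) return(.decode_outcome("failure"))
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  pos <- unname(hits[1L, 1L]); e <- unname(hits[1L, 2L]); d <- unname(hits[1L, 3L])
  corrected <- r
  corrected[pos] <- if (ring) (corrected[pos] + d) %% 4L
                    else bitwXor(corrected[pos], d)
  out <- .decode_outcome("corrected", pos, e, corrected)
  out$ambiguous <- nrow(hits) > 1L
  out
}
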