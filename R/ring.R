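# The Galois ring GR(4,m) = Z4[x]/(h(x)) for the monic basic irreducible h
# obtained as the Graeffe lift of a binary primitive polynomial.  Elements
# are coefficient vectors of length m over Z4.  The residue of x is the
# Teichmuller unit xi of multiplicative order 2^m - 1; reduction mod 2 maps
# GR(4,m) onto GF(2^m) and xi onto a primitive element, which gives the
# discrete logs used by the ring decoder.

.gr_pack2 <- function(v) as.integer(sum((as.integer(v) %% 2L) * 2^(seq_along(v) - 1)))

#' Build a GR(4,m) context
#'
#' Constructs the Galois ring GR(4,m) from a binary primitive polynomial:
#' the basic irreducible modulus is its Graeffe lift to Z4, the Teichmuller
#' unit \eqn{\xi} is the residue of \eqn{x}.  Precomputes the power table
#' \eqn{\xi^0,\dots,\xi^{n-1}} (\eqn{n = 2^m - 1}) and log/antilog tables
#' of the mod-2 image field GF(2^m).  Verifies that \eqn{\xi} has order
#' exactly \eqn{n}.
#'
#' @param binary_primitive an \code{sga_poly} over \code{"F2"} (or string),
#'   monic primitive of degree m with nonzero constant term.
#' @return an object of class \code{ring_context} with components \code{m},
#'   \code{n}, \code{binary_primitive}, \code{basic_irreducible},
#'   \code{xi_pow} (an \eqn{n \times m} matrix, row \eqn{j+1} holding the
#'   Z4 coordinates of \eqn{\xi^j}) and \code{gf2_log}.
#' @export
ring_context <- function(binary_primitive) {
  if (is.character(binary_primitive))
    binary_primitive <- parse_poly(binary_primitive, "F2")
  stopifnot(inherits(binary_primitive, "sga_poly"))
  if (binary_primitive$domain != "F2")
    stop("binary_primitive must be over F2")
  m <- poly_degree(binary_primitive)
  if (!is.finite(m) || m < 2L) stop("degree must be at least 2")
  basic <- graeffe_lift(binary_primitive)
  tail_neg <- (4L - basic$coef[1:m]) %% 4L      # x^m = -tail in GR(4,m)
  n <- as.integer(2^m - 1)
  mulx <- function(v) {
    c <- v[m]
    w <- c(0L, v[-m])
    if (c != 0L) w <- (w + c * tail_neg) %% 4L
    w
  }
  xi_pow <- matrix(0L, nrow = n, ncol = m)
  e <- c(1L, integer(m - 1L))
  xi_pow[1L, ] <- e
  for (j in 2:n) {
    e <- mulx(e)
    if (all(e == c(1L, integer(m - 1L))))
      stop("Teichmuller unit order ", j - 1L, " < ", n,
           ": binary polynomial is not primitive")
    xi_pow[j, ] <- e
  }
  if (!all(mulx(e) == c(1L, integer(m - 1L))))
    stop("internal error: xi^n != 1")
  # mod-2 image: packed binary vectors indexed by value + 1 -> discrete log
  gf2_log <- rep(NA_integer_, as.integer(2^m))
  packs <- apply(xi_pow %% 2L, 1L, function(v) .gr_pack2(v))
  if (anyDuplicated(packs)) stop("internal error: mod-2 images not distinct")
  gf2_log[packs + 1L] <- 0:(n - 1L)
  structure(list(m = m, n = n,
                 binary_primitive = binary_primitive,
                 basic_irreducible = basic,
                 xi_pow = xi_pow, gf2_log = gf2_log),
            class = "ring_context")
}

#' Power of the Teichmuller unit
#'
#' Returns \eqn{\xi^{e}} in GR(4,m), with the exponent reduced modulo
#' \eqn{n = 2^m - 1} (table lookup).
#'
#' @param ctx a \code{ring_context}.
#' @param exponent any integer.
#' @return integer vector of the m Z4 coordinates of \eqn{\xi^e}.
#' @export
ring_pow <- function(ctx, exponent) {
  stopifnot(inherits(ctx, "ring_context"))
  ctx$xi_pow[(as.integer(exponent %% ctx$n)) + 1L, ]
}

#' Multiply two elements of GR(4,m)
#'
#' Coefficient-vector multiplication modulo the basic irreducible, mod 4.
#'
#' @param ctx a \code{ring_context}.
#' @param u,v integer vectors of m Z4 coordinates.
#' @return integer vector of m Z4 coordinates.
#' @export
ring_mul <- function(ctx, u, v) {
  stopifnot(inherits(ctx, "ring_context"))
  prod <- .vec_mul(as.integer(u) %% 4L, as.integer(v) %% 4L, "Z4")
  r <- .vec_divmod(prod, ctx$basic_irreducible$coef, "Z4")$r
  c(r, integer(ctx$m - length(r)))
}

#' Evaluate a polynomial at a field or ring element
#'
#' Horner evaluation of a polynomial over Z4, GF4 or F2 at an element of
#' the extension algebra given by \code{ctx}.  Over a \code{ring_context}
#' the coefficients are taken mod 4; over a \code{field_context} the
#' coefficients are the GF(4) constants embedded in GF(4^m).
#'
#' @param p an \code{sga_poly}.
#' @param point the evaluation point as a coordinate vector of length m
#'   (e.g. \code{ring_pow(ctx, j)}), or a length-1 constant.
#' @param ctx a \code{ring_context} or \code{field_context}.
#' @return coordinate vector of length m with the value.
#' @export
eval_poly <- function(p, point, ctx) {
  stopifnot(inherits(p, "sga_poly"))
  if (inherits(ctx, "ring_context")) {
    if (p$domain == "GF4") stop("cannot evaluate a GF4 polynomial in GR(4,m)")
    m <- ctx$m
    pt <- as.integer(point)
    if (length(pt) == 1L) pt <- c(pt, integer(m - 1L))
    stopifnot(length(pt) == m)
    acc <- integer(m)
    for (cf in rev(p$coef)) {
      acc <- ring_mul(ctx, acc, pt)
      acc[1L] <- (acc[1L] + cf) %% 4L
    }
    acc %% 4L
  } else if (inherits(ctx, "field_context")) {
    if (p$domain == "Z4") stop("cannot evaluate a Z4 polynomial in GF(4^m)")
    m <- ctx$m
    pt <- as.integer(point)
    packed <- if (length(pt) == 1L) pt else .fq_pack(pt)
    acc <- 0L
    for (cf in rev(p$coef)) {
      acc <- bitwXor(.fq_mul(ctx, acc, packed), cf)
    }
    .fq_unpack(acc, m)
  } else stop("ctx must be a ring_context or field_context")
}

#' @export
print.ring_context <- function(x, ...) {
  cat("GR(4,", x$m, ") with basic irreducible ",
      format(x$basic_irreducible), " (lift of ",
      format(x$binary_primitive), "; n = ", x$n, ")\n", sep = "")
  invisible(x)
}
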