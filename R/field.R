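# GF(4^m) = GF(4)[x]/(p(x)) for a primitive p of degree m over GF(4).
# Elements are coefficient vectors of length m over GF(4); internally they
# are packed into a single integer, 2 bits per GF(4) coefficient, so that
# addition of packed elements is bitwise XOR.  Multiplication goes through
# discrete log/antilog tables of the primitive element alpha (the residue
# of x), which generates the 4^m - 1 nonzero elements.

.fq_pack <- function(v) as.integer(sum(as.integer(v) * 4^(seq_along(v) - 1)))

.fq_unpack <- function(x, m) as.integer((x %/% 4^(0:(m - 1))) %% 4)

#' Build a GF(4^m) context
#'
#' Constructs the extension field GF(4^m) from a primitive polynomial over
#' GF(4), with the primitive element \eqn{\alpha} the residue of \eqn{x}.
#' Precomputes antilog (\code{pow}) and discrete-log tables used by the
#' syndrome decoder.  Errors if the polynomial's root does not have full
#' multiplicative order \eqn{4^m - 1}, i.e. if the polynomial is not
#' primitive.
#'
#' @param primitive an \code{sga_poly} over \code{"GF4"} (or a string,
#'   parsed as GF4), monic of degree m.
#' @return an object of class \code{field_context} with components
#'   \code{m}, \code{n} (\eqn{4^m-1}), \code{primitive}, \code{pow}
#'   (packed \eqn{\alpha^0,\dots,\alpha^{n-1}}), \code{log}.
#' @export
field_context <- function(primitive) {
  if (is.character(primitive)) primitive <- parse_poly(primitive, "GF4")
  stopifnot(inherits(primitive, "sga_poly"))
  if (primitive$domain != "GF4") stop("primitive polynomial must be over GF4")
  m <- poly_degree(primitive)
  if (!is.finite(m) || m < 2L) stop("degree must be at least 2")
  coef <- primitive$coef
  if (coef[length(coef)] != 1L) stop("primitive polynomial must be monic")
  tail <- coef[1:m]                       # x^m = tail (char 2: -tail = tail)
  n <- as.integer(4^m - 1)
  # multiply a coefficient-vector element by x and reduce
  mulx <- function(v) {
    c <- v[m]
    w <- c(0L, v[-m])
    if (c != 0L) w <- bitwXor(w, gf4_mul(c, tail))
    w
  }
  pow <- integer(n)
  e <- c(1L, integer(m - 1L))
  pow[1L] <- .fq_pack(e)
  for (j in 2:n) {
    e <- mulx(e)
    p <- .fq_pack(e)
    if (p == 1L) stop("polynomial is not primitive: root order ", j - 1L,
                      " < ", n)
    pow[j] <- p
  }
  if (.fq_pack(mulx(e)) != 1L)
    stop("internal error: alpha^n != 1")
  logt <- rep(NA_integer_, as.integer(4^m))
  logt[pow + 1L] <- 0:(n - 1L)
  structure(list(m = m, n = n, primitive = primitive,
                 pow = pow, log = logt),
            class = "field_context")
}

# packed multiplication in GF(4^m)
.fq_mul <- function(ctx, x, y) {
  if (x == 0L || y == 0L) return(0L)
  ctx$pow[((ctx$log[x + 1L] + ctx$log[y + 1L]) %% ctx$n) + 1L]
}

#' @export
print.field_context <- function(x, ...) {
  cat("GF(4^", x$m, ") with primitive polynomial ", format(x$primitive),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
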