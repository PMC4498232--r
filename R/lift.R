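#' Graeffe (Hensel) lift of a binary primitive polynomial to Z4
#'
#' Lifts a monic binary polynomial \eqn{f_2} with nonzero constant term to
#' the unique monic polynomial \eqn{h} over Z4 with \eqn{h \equiv f_2
#' \pmod 2} whose roots are Teichmuller elements of the Galois ring
#' GR(4, deg f2).  Writing \eqn{f_2(x) = e(x^2) + x\,d(x^2)}, the lift is
#' \eqn{h(y) = \pm(e(y)^2 - y\,d(y)^2) \bmod 4}, the sign chosen so that
#' \eqn{h} is monic.  When \eqn{f_2} is primitive, a root of \eqn{h} is a
#' Teichmuller unit of order \eqn{2^{\deg f_2} - 1}, so \eqn{h} generates a
#' single-error-correcting BCH code over Z4 of length \eqn{2^m - 1}.
#'
#' @param f2 an \code{sga_poly} over \code{"F2"} (or a polynomial string,
#'   parsed over F2): monic, with nonzero constant term.
#' @return the lift as an \code{sga_poly} over \code{"Z4"}.
#' @examples
#' format(graeffe_lift("x^6+x^4+x^3+x+1"))   # "x^6+2x^5+x^4+x^3+3x+1"
#' @export
graeffe_lift <- function(f2) {
  if (is.character(f2)) f2 <- parse_poly(f2, "F2")
  stopifnot(inherits(f2, "sga_poly"))
  if (f2$domain != "F2") stop("graeffe_lift expects a binary polynomial")
  coef <- f2$coef
  deg <- length(coef) - 1L
  if (deg < 1L) stop("degree must be at least 1")
  if (coef[length(coef)] != 1L) stop("polynomial must be monic")
  if (coef[1L] == 0L) stop("polynomial must have nonzero constant term")
  e <- coef[seq(1L, length(coef), by = 2L)]          # even-degree part
  d <- if (length(coef) > 1L) coef[seq(2L, length(coef), by = 2L)] else integer(0)
  e2 <- .vec_mul(e, e, "Z4")
  d2 <- .vec_mul(d, d, "Z4")
  yd2 <- if (length(d2)) c(0L, d2) else integer(0)
  n <- max(length(e2), length(yd2))
  e2 <- c(e2, integer(n - length(e2)))
  yd2 <- c(yd2, integer(n - length(yd2)))
  h <- (e2 - yd2) %% 4L
  # odd degree: the leading term comes from -y d(y)^2, so negate to monic
  if (deg %% 2L == 1L) h <- (4L - h) %% 4L
  h <- .vec_trim(h)
  if (length(h) - 1L != deg || h[length(h)] != 1L)
    stop("internal error: lift is not monic of the input degree")
  sga_poly(h, "Z4")
}
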