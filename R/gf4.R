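# GF(4) = GF(2)[t]/(t^2 + t + 1), elements encoded as integers:
#   0 -> 0, 1 -> 1, 2 -> a (the class of t), 3 -> b = a + 1 = a^2.
# Addition is coefficient-wise over GF(2), i.e. bitwise XOR on the encoding;
# every element is its own additive inverse (Klein four-group).

# multiplication table, [x+1, y+1]; nonzero elements are the cyclic group
# {1, a, b} with a^2 = b, a*b = 1.
.GF4_MUL <- matrix(
  c(0L, 0L, 0L, 0L,
    0L, 1L, 2L, 3L,
    0L, 2L, 3L, 1L,
    0L, 3L, 1L, 2L),
  nrow = 4, byrow = TRUE
)

# discrete log base a for 1,2,3 (index by value)
.GF4_LOG <- c(NA_integer_, 0L, 1L, 2L)

#' Multiply elements of GF(4)
#'
#' GF(4) is represented as the integers 0--3 with \code{2 = a}, \code{3 = b
#' = a + 1}, arithmetic modulo \eqn{t^2 + t + 1} over GF(2).  Vectorised with
#' the usual recycling rules.
#'
#' @param x,y integer vectors with values in \code{0:3}.
#' @return integer vector of products in the same encoding.
#' @examples
#' gf4_mul(2, 2) # a * a = b = 3
#' gf4_mul(2, 3) # a * b = 1
#' @export
gf4_mul <- function(x, y) {
  stopifnot(all(x %in% 0:3), all(y %in% 0:3))
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n)
  y <- rep_len(as.integer(y), n)
  .GF4_MUL[cbind(x + 1L, y + 1L)]
}

#' Add elements of GF(4)
#'
#' Addition in GF(4) is bitwise XOR on the integer encoding (characteristic
#' two: \code{x + x = 0}).
#'
#' @inheritParams gf4_mul
#' @return integer vector of sums.
#' @export
gf4_add <- function(x, y) {
  stopifnot(all(x %in% 0:3), all(y %in% 0:3))
  bitwXor(as.integer(x), as.integer(y))
}

# multiplicative inverse of a nonzero GF(4) element
gf4_inv <- function(x) {
  stopifnot(all(x %in% 1:3))
  c(1L, 3L, 2L)[x]
}
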