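# Polynomials over F2, GF4 (encoding of gf4.R) or Z4, stored as integer
# coefficient vectors in ASCENDING degree order; the zero polynomial is
# integer(0) with degree -Inf.  All public printing/parsing uses the
# descending "c x^k" dialect of the code tables ("x^6+2x^5+x^4+x^3+3x+1").

.POLY_DOMAINS <- c("F2", "GF4", "Z4")

.domain_max <- function(domain) if (domain == "F2") 1L else 3L

# coefficient-wise addition in the given domain
.coef_add <- function(x, y, domain) {
  if (domain == "Z4") (x + y) %% 4L else bitwXor(x, y)
}

# coefficient-wise multiplication
.coef_mul <- function(x, y, domain) {
  switch(domain,
    Z4  = (x * y) %% 4L,
    GF4 = gf4_mul(x, y),
    F2  = (x * y) %% 2L
  )
}

.coef_neg <- function(x, domain) {
  if (domain == "Z4") (4L - x) %% 4L else x
}

#' Construct a polynomial
#'
#' @param coef integer coefficients in ascending degree order
#'   (\code{coef[1]} is the constant term).  For domain \code{"GF4"} the
#'   encoding is \code{0,1,2=a,3=b}.
#' @param domain one of \code{"F2"}, \code{"GF4"}, \code{"Z4"}.
#' @return an object of class \code{sga_poly}.
#' @export
sga_poly <- function(coef, domain = c("Z4", "GF4", "F2")) {
  domain <- match.arg(domain)
  coef <- as.integer(coef)
  if (any(is.na(coef)) || any(coef < 0L) || any(coef > .domain_max(domain)))
    stop("coefficients outside domain ", domain)
  while (length(coef) && coef[length(coef)] == 0L)
    coef <- coef[-length(coef)]
  structure(list(coef = coef, domain = domain), class = "sga_poly")
}

#' Degree of a polynomial
#'
#' @param p an \code{sga_poly}.
#' @return integer degree, or \code{-Inf} for the zero polynomial.
#' @export
poly_degree <- function(p) {
  stopifnot(inherits(p, "sga_poly"))
  if (length(p$coef) == 0L) -Inf else length(p$coef) - 1L
}

#' Parse a polynomial string
#'
#' Accepts the dialect used throughout the code tables: terms
#' \code{c x^k} joined by \code{+}, coefficient omitted when 1, exponent
#' omitted for \eqn{x} and constants; GF(4) coefficients may be the letters
#' \code{a} and \code{b}.  \code{parse_poly(format(p))} is the identity.
#'
#' @param text polynomial string, e.g. \code{"x^6+2x^5+x^4+x^3+3x+1"}.
#' @param domain coefficient domain, one of \code{"Z4"}, \code{"GF4"},
#'   \code{"F2"}.
#' @return an \code{sga_poly}.
#' @examples
#' parse_poly("x^6+2x^5+x^4+x^3+3x+1", "Z4")
#' parse_poly("x^3+ax^2+bx+b", "GF4")
#' @export
parse_poly <- function(text, domain = c("Z4", "GF4", "F2")) {
  domain <- match.arg(domain)
  raw <- gsub("[[:space:]]+", "", text)
  if (raw == "" ) stop("empty polynomial string")
  if (raw == "0") return(sga_poly(integer(0), domain))
  terms <- strsplit(raw, "+", fixed = TRUE)[[1]]
  if (any(terms == "")) stop("malformed polynomial string: empty term in '", text, "'")
  coef <- integer(0)
  seen <- integer(0)
  for (term in terms) {
    m <- regmatches(term, regexec("^([0-9ab]*)(x(\\^([0-9]+))?)?$", term))[[1]]
    if (length(m) == 0L || m[1] != term)
      stop("malformed term '", term, "' in polynomial string")
    cstr <- m[2]; xpart <- m[3]; estr <- m[5]
    if (cstr == "" && xpart == "")
      stop("malformed term '", term, "' in polynomial string")
    expo <- if (xpart == "") 0L else if (estr == "") 1L else as.integer(estr)
    cval <- if (cstr == "") 1L
            else if (cstr == "a") 2L
            else if (cstr == "b") 3L
            else suppressWarnings(as.integer(cstr))
    if (is.na(cval)) stop("malformed coefficient in term '", term, "'")
    if (cstr %in% c("a", "b") && domain != "GF4")
      stop("coefficient '", cstr, "' outside domain ", domain, " in term '", term, "'")
    if (cval > .domain_max(domain))
      stop("coefficient ", cval, " outside domain ", domain, " in term '", term, "'")
    if (expo %in% seen)
      stop("repeated exponent ", expo, " in term '", term, "'")
    seen <- c(seen, expo)
    if (length(coef) < expo + 1L)
      coef <- c(coef, integer(expo + 1L - length(coef)))
    coef[expo + 1L] <- cval
  }
  sga_poly(coef, domain)
}

#' @export
#' @method format sga_poly
format.sga_poly <- function(x, ...) {
  coef <- x$coef
  if (length(coef) == 0L) return("0")
  letters_gf4 <- c("0", "1", "a", "b")
  out <- character(0)
  for (i in seq(length(coef), 1L)) {
    cv <- coef[i]
    if (cv == 0L) next
    deg <- i - 1L
    cs <- if (x$domain == "GF4") letters_gf4[cv + 1L] else as.character(cv)
    term <- if (deg == 0L) cs
            else {
              xs <- if (deg == 1L) "x" else paste0("x^", deg)
              if (cv == 1L) xs else paste0(cs, xs)
            }
    out <- c(out, term)
  }
  paste(out, collapse = "+")
}

#' @export
print.sga_poly <- function(x, ...) {
  cat(format(x), " [", x$domain, "]\n", sep = "")
  invisible(x)
}

#' @export
`==.sga_poly` <- function(e1, e2) {
  identical(e1$domain, e2$domain) && identical(e1$coef, e2$coef)
}

# -- internal arithmetic on raw ascending coefficient vectors --------------

.vec_trim <- function(v) {
  while (length(v) && v[length(v)] == 0L) v <- v[-length(v)]
  v
}

.vec_add <- function(u, v, domain) {
  n <- max(length(u), length(v))
  u <- c(u, integer(n - length(u)))
  v <- c(v, integer(n - length(v)))
  .vec_trim(.coef_add(u, v, domain))
}

.vec_mul <- function(u, v, domain) {
  if (length(u) == 0L || length(v) == 0L) return(integer(0))
  r <- integer(length(u) + length(v) - 1L)
  for (i in seq_along(u)) {
    if (u[i] == 0L) next
    prod <- .coef_mul(u[i], v, domain)
    idx <- i:(i + length(v) - 1L)
    r[idx] <- .coef_add(r[idx], prod, domain)
  }
  .vec_trim(r)
}

# long division: returns list(q, r); divisor must have invertible leading
# coefficient (monic required over Z4 unless leading is a unit 1 or 3)
.vec_divmod <- function(num, den, domain) {
  den <- .vec_trim(den)
  if (length(den) == 0L) stop("division by zero polynomial")
  lead <- den[length(den)]
  lead_inv <- switch(domain,
    Z4  = if (lead == 1L) 1L else if (lead == 3L) 3L
          else stop("divisor leading coefficient not a unit in Z4"),
    GF4 = gf4_inv(lead),
    F2  = 1L
  )
  r <- num
  dd <- length(den) - 1L
  q <- integer(max(0L, length(num) - dd))
  while (length(r) >= length(den) && length(r) > 0L) {
    shift <- length(r) - length(den)
    factor <- .coef_mul(r[length(r)], lead_inv, domain)
    q[shift + 1L] <- factor
    sub <- .coef_mul(factor, den, domain)
    idx <- (shift + 1L):length(r)
    r[idx] <- .coef_add(r[idx], .coef_neg(sub, domain), domain)
    r <- .vec_trim(r)
  }
  list(q = .vec_trim(q), r = r)
}

#' Polynomial quotient and remainder
#'
#' Long division in the polynomial ring over the common coefficient domain.
#' Over Z4 the divisor's leading coefficient must be a unit (1 or 3); over
#' the fields any nonzero divisor works.
#'
#' @param num,den \code{sga_poly} objects over the same domain.
#' @return list with \code{sga_poly} components \code{quotient},
#'   \code{remainder}.
#' @export
poly_divmod <- function(num, den, domain = NULL) {
  stopifnot(inherits(num, "sga_poly"), inherits(den, "sga_poly"))
  if (num$domain != den$domain) stop("domain mismatch")
  qr <- .vec_divmod(num$coef, den$coef, num$domain)
  list(quotient = sga_poly(qr$q, num$domain),
       remainder = sga_poly(qr$r, num$domain))
}

#' Polynomial product
#' @param p,q \code{sga_poly} objects over the same domain.
#' @return their product as an \code{sga_poly}.
#' @export
poly_mul <- function(p, q) {
  stopifnot(inherits(p, "sga_poly"), inherits(q, "sga_poly"))
  if (p$domain != q$domain) stop("domain mismatch")
  sga_poly(.vec_mul(p$coef, q$coef, p$domain), p$domain)
}

#' Polynomial sum
#' @inheritParams poly_mul
#' @return their sum as an \code{sga_poly}.
#' @export
poly_add <- function(p, q) {
  stopifnot(inherits(p, "sga_poly"), inherits(q, "sga_poly"))
  if (p$domain != q$domain) stop("domain mismatch")
  sga_poly(.vec_add(p$coef, q$coef, p$domain), p$domain)
}
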