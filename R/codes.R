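# Single-error-correcting BCH codes from the built-in preset registry.
# A symbol vector of length n stores, at position i (1-based), the
# coefficient of x^(n-i): the leftmost symbol is the highest degree.  This
# convention is fixed everywhere; reported error positions are therefore
# 1-based sequence coordinates.

.registry_cache <- new.env(parent = emptyenv())

#' Built-in code presets
#'
#' Returns the registry of code presets: one row per preset with its key,
#' sequence class (TS targeting sequence, PM protein motif, ? unstated),
#' GI number and organism of the sequence the preset was derived for, the
#' labeling name, the algebra kind (\code{R} ring / \code{F} field) and the
#' primitive and generator polynomial strings.
#'
#' @return a data.frame with 15 rows.
#' @export
code_registry <- function() {
  if (is.null(.registry_cache$reg)) {
    path <- system.file("extdata", "code_registry.tsv", package = "dnasga")
    .registry_cache$reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                                             colClasses = "character")
  }
  .registry_cache$reg
}

.registry_entry <- function(key) {
  reg <- code_registry()
  i <- match(key, reg$key)
  if (is.na(i)) stop("unknown code preset '", key, "'; see code_registry()")
  as.list(reg[i, ])
}

#' Construct a code from a preset or explicit parameters
#'
#' Builds a single-error-correcting BCH code (designed distance 3) over
#' GF(4^m) (\code{kind = "field"}) or the Galois ring GR(4,m)
#' (\code{kind = "ring"}).  For ring codes the length is \eqn{n = 2^m - 1}
#' and the expected generator is the Graeffe lift of the binary primitive
#' polynomial; for field codes \eqn{n = 4^m - 1} and the expected generator
#' is the product of the minimal polynomials of \eqn{\alpha} and
#' \eqn{\alpha^2}.  A printed generator that does not match the derived one
#' is kept (the preset table is treated as ground truth) with a recorded
#' warning; a generator that does not divide \eqn{x^n - 1} is an error.
#' A preset flagged ring whose primitive polynomial has GF(4) coefficients
#' is constructed as a field code, with a warning.
#'
#' @param entry a preset key from \code{code_registry()} (e.g.
#'   \code{"S02.b"}, \code{"MDH"}), or a list with components
#'   \code{kind} ("R"/"F"), \code{primitive}, \code{generator} (strings;
#'   \code{generator} may be NULL to use the derived one), optional
#'   \code{key}, \code{labeling}.
#' @return an object of class \code{sga_code} with components \code{key},
#'   \code{kind}, \code{m}, \code{n}, \code{k}, \code{d}, \code{primitive},
#'   \code{generator}, \code{ctx}, \code{default_labeling}, \code{notes}.
#' @examples
#' code <- build_code("S02.b")
#' code$n; code$k
#' @export
build_code <- function(entry) {
  if (is.character(entry) && length(entry) == 1L) entry <- .registry_entry(entry)
  stopifnot(is.list(entry), !is.null(entry$kind), !is.null(entry$primitive))
  notes <- character(0)
  kind <- switch(toupper(entry$kind), R = "ring", RING = "ring",
                 F = "field", FIELD = "field",
                 stop("kind must be 'R' or 'F'"))
  if (kind == "ring" && grepl("[ab]", entry$primitive)) {
    notes <- c(notes, paste0(
      "preset flagged ring but primitive polynomial '", entry$primitive,
      "' is over GF(4); constructed as a field code"))
    warning(notes[length(notes)], call. = FALSE)
    kind <- "field"
  }
  if (kind == "ring") {
    primitive <- parse_poly(entry$primitive, "F2")
    ctx <- ring_context(primitive)
    derived <- ctx$basic_irreducible
    generator <- if (is.null(entry$generator)) derived
                 else parse_poly(entry$generator, "Z4")
    gdom <- "Z4"
  } else {
    primitive <- parse_poly(entry$primitive, "GF4")
    ctx <- field_context(primitive)
    derived <- derive_generator(ctx)
    generator <- if (is.null(entry$generator)) derived
                 else parse_poly(entry$generator, "GF4")
    gdom <- "GF4"
  }
  if (!(generator == derived)) {
    notes <- c(notes, paste0("printed generator ", format(generator),
                             " differs from derived ", format(derived)))
    warning(notes[length(notes)], call. = FALSE)
  }
  n <- ctx$n
  # generator must divide x^n - 1
  xn1 <- sga_poly(c(if (gdom == "Z4") 3L else 1L, integer(n - 1L), 1L), gdom)
  if (poly_degree(poly_divmod(xn1, generator)$remainder) != -Inf)
    stop("invalid code: generator does not divide x^n - 1 (n = ", n, ")")
  k <- n - poly_degree(generator)
  code <- structure(list(
    key = if (!is.null(entry$key)) entry$key else NA_character_,
    kind = kind, m = ctx$m, n = n, k = k, d = 3L,
    primitive = primitive, generator = generator, ctx = ctx,
    default_labeling = if (!is.null(entry$labeling)) entry$labeling else NA_character_,
    notes = notes,
    cache = new.env(parent = emptyenv())
  ), class = "sga_code")
  # syndrome lookup structures: position i of the symbol vector carries
  # x^(n-i), so s1 uses beta^(n-i) and s2 uses beta^(2(n-i))
  pos_exp <- (n - seq_len(n)) %% n
  if (kind == "ring") {
    code$S1mat <- ctx$xi_pow[pos_exp + 1L, , drop = FALSE]
    code$S2mat <- ctx$xi_pow[((2L * pos_exp) %% n) + 1L, , drop = FALSE]
  } else {
    code$pos_exp1 <- pos_exp
    code$pos_exp2 <- (2L * pos_exp) %% n
  }
  code
}

#' @export
print.sga_code <- function(x, ...) {
  cat("BCH code ", if (!is.na(x$key)) paste0("[", x$key, "] ") else "",
      "(", x$n, ", ", x$k, ", ", x$d, ") over ",
      if (x$kind == "ring") paste0("GR(4,", x$m, ")") else paste0("GF(4^", x$m, ")"),
      "\n  primitive polynomial: ", format(x$primitive),
      "\n  generator polynomial: ", format(x$generator), "\n", sep = "")
  for (note in x$notes) cat("  note: ", note, "\n", sep = "")
  invisible(x)
}

#' Derive the generator polynomial from a context
#'
#' Field case: the product of the minimal polynomials over GF(4) of
#' \eqn{\alpha} and \eqn{\alpha^2} (conjugacy under the Frobenius
#' \eqn{x \mapsto x^4}).  Ring case: the basic irreducible, the minimal
#' polynomial of \eqn{\xi} over Z4, whose Teichmuller conjugates include
#' \eqn{\xi^2}.  Either way the two consecutive powers \eqn{\beta, \beta^2}
#' are roots, giving designed distance 3.
#'
#' @param ctx a \code{field_context} or \code{ring_context}.
#' @return monic \code{sga_poly} over GF4 (field) or Z4 (ring).
#' @export
derive_generator <- function(ctx) {
  if (inherits(ctx, "ring_context")) return(ctx$basic_irreducible)
  stopifnot(inherits(ctx, "field_context"))
  n <- ctx$n; m <- ctx$m
  conj <- function(s) {
    out <- integer(0); e <- s
    repeat { out <- c(out, e); e <- (e * 4L) %% n; if (e == s) break }
    out
  }
  roots <- ctx$pow[unique(c(conj(1L), conj(2L))) + 1L]
  # product of (x - alpha^c), coefficients in packed GF(4^m); char 2 so - = +
  poly <- 1L
  for (r in roots) {
    np <- integer(length(poly) + 1L)
    np[-1L] <- bitwXor(np[-1L], poly)
    np[seq_along(poly)] <- bitwXor(np[seq_along(poly)],
                                   vapply(poly, function(co) .fq_mul(ctx, co, r), integer(1)))
    poly <- np
  }
  if (any(poly > 3L))
    stop("internal error: derived generator has non-GF(4) coefficients")
  sga_poly(poly, "GF4")
}

#' Encode a message
#'
#' Non-systematic encoding: the codeword polynomial is
#' \eqn{m(x)\,g(x)}.  The output symbol vector (leftmost symbol = highest
#' degree) always satisfies \code{is_codeword}.
#'
#' @param message integer vector of k symbols (Z4 or GF4 encoding as the
#'   code's alphabet), \code{message[1]} the coefficient of \eqn{x^{k-1}}.
#' @param code an \code{sga_code}.
#' @return integer symbol vector of length n.
#' @export
encode <- function(message, code) {
  stopifnot(inherits(code, "sga_code"))
  message <- as.integer(message)
  if (length(message) != code$k)
    stop("message length ", length(message), " != k = ", code$k)
  if (any(message < 0L | message > 3L)) stop("symbols must be in 0..3")
  dom <- if (code$kind == "ring") "Z4" else "GF4"
  # .vec_mul loops over its first argument: pass the short generator first
  cw <- .vec_mul(code$generator$coef, rev(message), dom)   # ascending
  cw <- c(cw, integer(code$n - length(cw)))
  rev(cw)
}

# internal syndromes in the decoder's native representation:
# ring -> list of two m-vectors; field -> list of two packed integers
.syndromes_raw <- function(r, code) {
  n <- code$n
  if (code$kind == "ring") {
    s1 <- as.integer(r %*% code$S1mat) %% 4L
    s2 <- as.integer(r %*% code$S2mat) %% 4L
    list(s1 = s1, s2 = s2)
  } else {
    ctx <- code$ctx
    nz <- which(r != 0L)
    xr <- function(idx) Reduce(bitwXor, idx, 0L)
    lg <- .GF4_LOG_FIELD(ctx)[r[nz] + 1L]
    s1 <- xr(ctx$pow[((lg + code$pos_exp1[nz]) %% n) + 1L])
    s2 <- xr(ctx$pow[((lg + code$pos_exp2[nz]) %% n) + 1L])
    list(s1 = s1, s2 = s2)
  }
}

# logs of the GF(4) constants 0..3 inside GF(4^m) (index value+1; 0 -> NA)
.GF4_LOG_FIELD <- function(ctx) ctx$log[1:4]

#' Syndromes of a symbol vector
#'
#' Evaluates the received polynomial \eqn{r(x)} at \eqn{\beta} and
#' \eqn{\beta^2}, where \eqn{\beta} is the primitive element \eqn{\alpha}
#' (field) or the Teichmuller unit \eqn{\xi} (ring).  A vector is a
#' codeword exactly when both syndromes vanish.
#'
#' @param r integer symbol vector of length n.
#' @param code an \code{sga_code}.
#' @return list with components \code{s1}, \code{s2}, each an integer
#'   coordinate vector of length m.
#' @export
syndromes <- function(r, code) {
  stopifnot(inherits(code, "sga_code"))
  r <- .check_symbols(r, code)
  s <- .syndromes_raw(r, code)
  if (code$kind == "field") {
    s$s1 <- .fq_unpack(s$s1, code$m)
    s$s2 <- .fq_unpack(s$s2, code$m)
  }
  s
}

.check_symbols <- function(r, code) {
  r <- as.integer(r)
  if (length(r) != code$n) stop("symbol vector length ", length(r),
                                " != n = ", code$n)
  if (any(r < 0L | r > 3L)) stop("symbols must be in 0..3")
  r
}

# remainder of the received polynomial modulo g (ascending coefficients)
.poly_remainder <- function(r, code) {
  dom <- if (code$kind == "ring") "Z4" else "GF4"
  .vec_divmod(rev(r), code$generator$coef, dom)$r
}

#' Test codeword membership
#'
#' True iff the received polynomial is divisible by the generator
#' polynomial.  Computed both by polynomial long division and by the
#' syndrome pair; the two routes are cross-checked and a disagreement is an
#' internal error.
#'
#' @inheritParams syndromes
#' @return logical scalar.
#' @export
is_codeword <- function(r, code) {
  stopifnot(inherits(code, "sga_code"))
  r <- .check_symbols(r, code)
  by_div <- length(.poly_remainder(r, code)) == 0L
  s <- .syndromes_raw(r, code)
  by_syn <- if (code$kind == "ring") all(s$s1 == 0L) && all(s$s2 == 0L)
            else s$s1 == 0L && s$s2 == 0L
  if (by_div != by_syn)
    stop("internal error: divisibility and syndrome membership disagree")
  by_div
}

#' Certify the minimum Hamming weight of a code
#'
#' Certifies that a designed-distance-3 code has minimum weight exactly 3:
#' (i) no nonzero codeword of weight 1 (\eqn{e\beta^j} never vanishes);
#' (ii) no codeword of weight 2 -- by cyclicity the support may be rotated
#' to contain degree 0, and all \eqn{9(n-1)} two-term patterns
#' \eqn{e_1 + e_2\beta^j} are exhausted against both syndromes over the
#' precomputed power tables (the BCH-bound argument made computational);
#' (iii) an explicit weight-3 codeword found by bounded search over
#' supports \eqn{\{0, j, k\}} with nonzero coefficients, solving for the
#' third term by discrete log.
#'
#' @param code an \code{sga_code} with designed distance 3.
#' @return object of class \code{sga_weight_certificate}: list with
#'   \code{no_weight_1}, \code{no_weight_2} (logicals), \code{weight3}
#'   (list: \code{positions} 1-based symbol positions, \code{degrees},
#'   \code{coefficients}, \code{vector}) and \code{min_weight}.
#' @export
min_weight_certificate <- function(code) {
  stopifnot(inherits(code, "sga_code"), code$d == 3L)
  n <- code$n
  ring <- code$kind == "ring"
  ctx <- code$ctx
  # -- weight 1: e * beta^j != 0 for all e in 1..3, all j
  no_w1 <- if (ring) {
    !any(vapply(1:3, function(e) {
      any(rowSums((e * ctx$xi_pow) %% 4L) == 0L)
    }, logical(1)))
  } else all(ctx$pow != 0L)
  # -- weight 2: e1 + e2 beta^j = 0 (both syndromes) has no solution, j in 1..n-1
  found_w2 <- FALSE
  for (e1 in 1:3) for (e2 in 1:3) {
    if (ring) {
      s1 <- (e2 * ctx$xi_pow[2:n, , drop = FALSE]) %% 4L
      s1[, 1L] <- (s1[, 1L] + e1) %% 4L
      s2 <- (e2 * ctx$xi_pow[((2L * (1:(n - 1L))) %% n) + 1L, , drop = FALSE]) %% 4L
      s2[, 1L] <- (s2[, 1L] + e1) %% 4L
      if (any(rowSums(s1) == 0L & rowSums(s2) == 0L)) found_w2 <- TRUE
    } else {
      le2 <- ctx$log[e2 + 1L]
      j <- 1:(n - 1L)
      s1 <- bitwXor(e1, ctx$pow[((le2 + j) %% n) + 1L])
      s2 <- bitwXor(e1, ctx$pow[((le2 + 2L * j) %% n) + 1L])
      if (any(s1 == 0L & s2 == 0L)) found_w2 <- TRUE
    }
  }
  # -- weight 3: find e1 + e2 beta^j + e3 beta^k = 0 with both syndromes
  w3 <- NULL
  for (e1 in 1:3) {
    for (e2 in 1:3) {
      for (j in 1:(n - 2L)) {
        if (ring) {
          t1 <- (e2 * ctx$xi_pow[j + 1L, ]) %% 4L
          t1[1L] <- (t1[1L] + e1) %% 4L
          t1 <- (4L - t1) %% 4L
          t2 <- (e2 * ctx$xi_pow[((2L * j) %% n) + 1L, ]) %% 4L
          t2[1L] <- (t2[1L] + e1) %% 4L
          t2 <- (4L - t2) %% 4L
          if (all(t1 == 0L)) next
          if (any(t1 %% 2L == 1L)) {            # unit: e3 in {1,3}
            k <- ctx$gf2_log[.gr_pack2(t1 %% 2L) + 1L]
            if (is.na(k) || k <= j) next
            for (e3 in c(1L, 3L)) {
              ok1 <- all(t1 == (e3 * ctx$xi_pow[k + 1L, ]) %% 4L)
              ok2 <- all(t2 == (e3 * ctx$xi_pow[((2L * k) %% n) + 1L, ]) %% 4L)
              if (ok1 && ok2) { w3 <- list(e1, e2, e3, j, k); break }
            }
          } else {                               # 2 * Teichmuller: e3 = 2
            half <- (t1 %/% 2L) %% 2L
            if (all(half == 0L)) next
            k <- ctx$gf2_log[.gr_pack2(half) + 1L]
            if (is.na(k) || k <= j) next
            ok1 <- all(t1 == (2L * ctx$xi_pow[k + 1L, ]) %% 4L)
            ok2 <- all(t2 == (2L * ctx$xi_pow[((2L * k) %% n) + 1L, ]) %% 4L)
            if (ok1 && ok2) w3 <- list(e1, e2, 2L, j, k)
          }
        } else {
          le2 <- ctx$log[e2 + 1L]
          t1 <- bitwXor(e1, ctx$pow[((le2 + j) %% n) + 1L])
          t2 <- bitwXor(e1, ctx$pow[((le2 + 2L * j) %% n) + 1L])
          if (t1 == 0L) next
          for (e3 in 1:3) {
            k <- (ctx$log[t1 + 1L] - ctx$log[e3 + 1L]) %% n
            if (k <= j) next
            if (bitwXor(t2, ctx$pow[((ctx$log[e3 + 1L] + 2L * k) %% n) + 1L]) == 0L) {
              w3 <- list(e1, e2, e3, j, k); break
            }
          }
        }
        if (!is.null(w3)) break
      }
      if (!is.null(w3)) break
    }
    if (!is.null(w3)) break
  }
  if (is.null(w3)) stop("weight-3 search exhausted without a certificate")
  degrees <- c(0L, w3[[4L]], w3[[5L]])
  coefs <- c(w3[[1L]], w3[[2L]], w3[[3L]])
  vec <- integer(n)
  vec[n - degrees] <- coefs
  if (!is_codeword(vec, code))
    stop("internal error: weight-3 candidate is not a codeword")
  structure(list(code_key = code$key, no_weight_1 = no_w1,
                 no_weight_2 = !found_w2,
                 weight3 = list(positions = n - degrees, degrees = degrees,
                                coefficients = coefs, vector = vec),
                 min_weight = if (no_w1 && !found_w2) 3L else NA_integer_),
            class = "sga_weight_certificate")
}

#' @export
print.sga_weight_certificate <- function(x, ...) {
  cat("Minimum-weight certificate",
      if (!is.na(x$code_key)) paste0(" for [", x$code_key, "]") else "", ":\n",
      "  no nonzero codeword of weight 1: ", x$no_weight_1, "\n",
      "  no nonzero codeword of weight 2: ", x$no_weight_2, "\n",
      "  weight-3 codeword at degrees {",
      paste(x$weight3$degrees, collapse = ", "), "} with coefficients {",
      paste(x$weight3$coefficients, collapse = ", "), "}\n",
      "  minimum Hamming weight: ", x$min_weight, "\n", sep = "")
  invisible(x)
}
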