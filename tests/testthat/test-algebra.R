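# GF(4) arithmetic, polynomial parsing/printing, division, and the
# field/ring contexts.

test_that("GF(4) has Klein additive structure and cyclic multiplication", {
  expect_equal(gf4_mul(2, 2), 3)        # a * a = a + 1 = b
  expect_equal(gf4_mul(1, 3), 3)        # identity
  expect_equal(gf4_mul(2, 3), 1)        # a * b = 1
  for (x in 0:3) {
    expect_equal(gf4_add(x, x), 0)      # self-inverse addition
    for (y in 0:3) {
      expect_equal(gf4_add(x, y), gf4_add(y, x))
      expect_equal(gf4_mul(x, y), gf4_mul(y, x))
    }
  }
  # distributivity, exhaustive over all 64 triples
  for (x in 0:3) for (y in 0:3) for (z in 0:3)
    expect_equal(gf4_mul(x, gf4_add(y, z)),
                 gf4_add(gf4_mul(x, y), gf4_mul(x, z)))
  # nonzero elements form a cycle of order 3
  expect_equal(gf4_mul(gf4_mul(2, 2), 2), 1)
})

test_that("polynomial strings parse to the expected coefficients", {
  p <- parse_poly("x^6+2x^5+x^4+x^3+3x+1", "Z4")
  expect_equal(rev(p$coef), c(1, 2, 1, 1, 0, 3, 1))   # x^6 down to x^0
  expect_equal(poly_degree(p), 6)
  q <- parse_poly("x^3+ax^2+bx+b", "GF4")
  expect_equal(rev(q$coef), c(1, 2, 3, 3))            # 1, a, b, b
  z <- parse_poly("0", "Z4")
  expect_equal(poly_degree(z), -Inf)
  expect_equal(format(z), "0")
})

test_that("parse then print is the identity on canonical strings", {
  strings <- c("x^6+2x^5+x^4+x^3+3x+1", "x^10+x^9+x^8+3x^7+x^6+x^4+x^3+3x+1",
               "x^6+3x^5+2x^3+1", "3x+1", "x", "2", "0")
  for (s in strings)
    expect_identical(format(parse_poly(s, "Z4")), s)
  gf4_strings <- c("x^3+ax^2+bx+b", "x^3+bx^2+x+a", "ax^2+b", "x^6+x^5+1")
  for (s in gf4_strings)
    expect_identical(format(parse_poly(s, "GF4")), s)
  # random polynomials round-trip through their printed form
  set.seed(11)
  for (dom in c("Z4", "GF4", "F2")) {
    for (rep in 1:25) {
      coef <- sample(0:(if (dom == "F2") 1 else 3), sample(1:9, 1), replace = TRUE)
      p <- sga_poly(coef, dom)
      expect_true(parse_poly(format(p), dom) == p)
    }
  }
})

test_that("malformed polynomial strings raise errors naming the term", {
  expect_error(parse_poly("x^2+x^2", "Z4"), "repeated exponent")
  expect_error(parse_poly("5x", "Z4"), "outside domain")
  expect_error(parse_poly("ax", "Z4"), "outside domain")
  expect_error(parse_poly("x^2++1", "Z4"), "empty term")
  expect_error(parse_poly("x^", "Z4"), "malformed")
  expect_error(parse_poly("2x", "F2"), "outside domain")
})

test_that("polynomial division satisfies num = q*den + r with deg r < deg den", {
  set.seed(23)
  for (dom in c("Z4", "GF4")) {
    for (rep in 1:20) {
      num <- sga_poly(sample(0:3, sample(3:12, 1), replace = TRUE), dom)
      den <- sga_poly(c(sample(0:3, sample(1:4, 1), replace = TRUE), 1), dom)
      qr <- poly_divmod(num, den)
      expect_true(poly_degree(qr$remainder) < poly_degree(den))
      expect_true(poly_add(poly_mul(qr$quotient, den), qr$remainder) == num)
    }
  }
})

test_that("field context: alpha has exact order 4^m - 1", {
  ctx <- test_code("S02.a")$ctx
  expect_equal(ctx$n, 63)
  # alpha^j = 1 only at j = 0 within one period
  expect_equal(which(ctx$pow == 1L), 1L)
  # in particular no proper divisor of 63 is an order
  for (j in c(3, 7, 9, 21)) expect_false(ctx$pow[j + 1] == 1L)
  # the primitive polynomial annihilates alpha
  alpha <- c(0L, 1L, 0L)
  expect_equal(eval_poly(ctx$primitive, alpha, ctx), c(0L, 0L, 0L))
})

test_that("ring context: Teichmuller unit and conjugacy", {
  ctx <- test_code("S02.b")$ctx
  expect_equal(ctx$n, 63)
  expect_equal(ring_pow(ctx, 0), c(1L, rep(0L, 5)))
  expect_equal(ring_pow(ctx, 63), c(1L, rep(0L, 5)))    # xi^n = 1
  # exact order: the Teichmuller set {0, 1, xi, ..., xi^(n-1)} has 2^m elems
  expect_equal(nrow(unique(ctx$xi_pow)), 63)
  # basic irreducible reduced mod 2 equals the binary primitive
  expect_equal(ctx$basic_irreducible$coef %% 2L, ctx$binary_primitive$coef)
  # the basic irreducible annihilates xi and its Teichmuller conjugates
  for (e in c(1, 2, 4, 8, 16, 32))
    expect_equal(eval_poly(ctx$basic_irreducible, ring_pow(ctx, e), ctx),
                 rep(0L, 6))
  # and xi^2 is such a conjugate explicitly (BCH designed distance 3)
  expect_equal(eval_poly(ctx$basic_irreducible, ring_pow(ctx, 2), ctx),
               rep(0L, 6))
})

test_that("mod-2 reduction of GR(4,m) is a ring homomorphism", {
  ctx <- test_code("S02.b")$ctx
  set.seed(5)
  for (rep in 1:30) {
    u <- sample(0:3, 6, replace = TRUE)
    v <- sample(0:3, 6, replace = TRUE)
    expect_equal(ring_mul(ctx, u, v) %% 2L,
                 mod2_field_mul(ctx, u %% 2L, v %% 2L))
    # Frobenius compatibility: (u+v)^2 = u^2 + v^2 mod 2
    s <- (u + v) %% 4L
    lhs <- ring_mul(ctx, s, s) %% 2L
    rhs <- (ring_mul(ctx, u, u) + ring_mul(ctx, v, v)) %% 2L
    expect_equal(lhs, rhs)
  }
})

test_that("eval_poly handles degenerate inputs", {
  ctx <- test_code("S02.b")$ctx
  xi <- ring_pow(ctx, 1)
  expect_equal(eval_poly(sga_poly(integer(0), "Z4"), xi, ctx), rep(0L, 6))
  x2 <- sga_poly(c(0L, 0L, 1L), "Z4")
  expect_equal(eval_poly(x2, xi, ctx), ring_pow(ctx, 2))
  fctx <- test_code("S02.a")$ctx
  expect_error(eval_poly(sga_poly(1L, "Z4"), 1L, fctx), "Z4")
})
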