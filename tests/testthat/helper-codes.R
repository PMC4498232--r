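# Shared helpers: memoised code construction (contexts are cheap but the
# suite touches every preset many times) and symbol-level error injection.

.test_code_cache <- new.env(parent = emptyenv())

test_code <- function(key) {
  if (is.null(.test_code_cache[[key]]))
    .test_code_cache[[key]] <- suppressWarnings(build_code(key))
  .test_code_cache[[key]]
}

registry_keys_n63 <- function() {
  reg <- code_registry()
  reg$key[reg$key != "MDH"]
}

# add error value e (in the code's algebra) at symbol position i
add_error <- function(r, i, e, code) {
  r[i] <- if (code$kind == "ring") (r[i] + e) %% 4L else bitwXor(r[i], e)
  r
}

random_codeword <- function(code) {
  encode(sample(0:3, code$k, replace = TRUE), code)
}

# GF(2^m) multiplication done from scratch (school multiplication plus
# reduction by the binary primitive), independent of the package's tables
mod2_field_mul <- function(ctx, u, v) {
  r <- integer(length(u) + length(v) - 1L)
  for (i in seq_along(u)) {
    if (u[i] == 1L) {
      idx <- i:(i + length(v) - 1L)
      r[idx] <- bitwXor(r[idx], v)
    }
  }
  f2 <- ctx$binary_primitive$coef        # ascending, monic, degree m
  m <- length(f2) - 1L
  while (length(r) > m) {
    if (r[length(r)] == 1L) {
      idx <- (length(r) - m):length(r)
      r[idx] <- bitwXor(r[idx], f2)
    }
    r <- r[-length(r)]
  }
  c(r, integer(m - length(r)))
}

# a labeling to pair with a code in pipeline tests
code_labeling <- function(code) {
  sga_labeling(if (is.na(code$default_labeling)) "A" else code$default_labeling)
}
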