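# The DNA-facing pipeline: labelings, identification and batch scanning.

test_that("labelings are bijections and round-trip any sequence", {
  set.seed(71)
  for (lab in sga_labelings()) {
    expect_setequal(lab$map, 0:3)
    for (rep in 1:10) {
      seq <- paste(sample(c("A", "C", "G", "T"), 63, replace = TRUE),
                   collapse = "")
      expect_identical(invert_labeling(apply_labeling(seq, lab), lab), seq)
    }
  }
  # two labelings differing by a transposition disagree exactly where the
  # transposed nucleotides occur
  seq <- "ACGTACGTGG"
  va <- apply_labeling(seq, "A")   # G->2, T->3
  vb <- apply_labeling(seq, "B")   # G->3, T->2
  expect_equal(which(va != vb),
               which(strsplit(seq, "")[[1]] %in% c("G", "T")))
})

test_that("a homopolymer mapping to the zero vector is a codeword", {
  code <- test_code("S02.b")
  res <- identify_sequence(strrep("A", 63), code, "B")   # A -> 0
  expect_identical(res$status, "codeword")
  expect_identical(res$generated_sequence, res$input_sequence)
})

test_that("identification statuses cover codeword, cloud and unidentified", {
  set.seed(73)
  code <- test_code("S02.b")
  lab <- sga_labeling("B")
  cw_dna <- invert_labeling(random_codeword(code), lab)
  expect_identical(identify_sequence(cw_dna, code, lab)$status, "codeword")
  # plant one substitution at position 17
  mutated <- cw_dna
  ref <- substr(mutated, 17, 17)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  substr(mutated, 17, 17) <- alt
  res <- identify_sequence(mutated, code, lab)
  expect_identical(res$status, "cloud")
  expect_equal(res$position, 17)
  expect_identical(res$original_nt, alt)
  expect_identical(res$suggested_nt, ref)
  expect_identical(res$generated_sequence, cw_dna)
  # two substitutions, oracle-verified to be outside every cloud
  repeat {
    m2 <- mutated
    p2 <- sample(setdiff(1:63, 17), 1)
    r2 <- substr(m2, p2, p2)
    substr(m2, p2, p2) <- setdiff(c("A", "C", "G", "T"), r2)[1]
    if (brute_force_identify(apply_labeling(m2, lab), code)$status ==
        "failure") break
  }
  expect_identical(identify_sequence(m2, code, lab)$status, "unidentified")
})

test_that("every planted substitution is recovered, exhaustively per preset", {
  set.seed(79)
  bases <- c("A", "C", "G", "T")
  for (key in registry_keys_n63()) {
    code <- test_code(key)
    lab <- code_labeling(code)
    cw_dna <- invert_labeling(random_codeword(code), lab)
    for (pos in 1:63) {
      ref <- substr(cw_dna, pos, pos)
      for (alt in setdiff(bases, ref)) {
        mutated <- cw_dna
        substr(mutated, pos, pos) <- alt
        res <- identify_sequence(mutated, code, lab)
        expect_identical(res$status, "cloud")
        expect_equal(res$position, pos)
        expect_identical(res$suggested_nt, ref)
        # generated sequence differs from the input at exactly 1 nt
        d <- mapply(function(a, b) a != b,
                    strsplit(res$generated_sequence, "")[[1]],
                    strsplit(mutated, "")[[1]])
        expect_equal(sum(d), 1)
      }
    }
  }
})

test_that("rotating a cloud sequence rotates the reported position", {
  set.seed(83)
  code <- test_code("S02.b")
  lab <- sga_labeling("B")
  cw_dna <- invert_labeling(random_codeword(code), lab)
  mutated <- cw_dna
  ref <- substr(mutated, 30, 30)
  substr(mutated, 30, 30) <- setdiff(c("A", "C", "G", "T"), ref)[1]
  for (shift in c(1, 5, 40)) {
    rotated <- paste0(substr(mutated, shift + 1, 63), substr(mutated, 1, shift))
    res <- identify_sequence(rotated, code, lab)
    expect_identical(res$status, "cloud")
    expect_equal(res$position, ((30 - shift - 1) %% 63) + 1)
  }
})

test_that("scan gates by length and reports the planted preset", {
  set.seed(89)
  code <- test_code("S02.d")
  lab <- sga_labeling("C")
  fx <- generate_fixtures(code, lab, n_seq = 1, errors = 1, seed = 89)
  res <- scan_sequence(fx$sequences[1], id = "fx")
  expect_equal(nrow(res), 15)
  expect_identical(res$status[res$code_key == "MDH"], "skipped")
  hit <- res[res$code_key == "S02.d", ]
  expect_identical(hit$status, "cloud")
  expect_equal(hit$position_1based, fx$truth$planted_position)
  # 3.c shares the same code and labeling A; other presets may or may not
  # identify; all non-MDH rows must have run
  expect_true(all(res$status[res$code_key != "MDH"] %in%
                  c("codeword", "cloud", "unidentified")))
  expect_equal(nrow(scan_sequence("ACGT", keys = character(0))), 0)
})

test_that("length mismatches are strict unless pad/truncate is requested", {
  code <- test_code("S02.b")
  short <- strrep("A", 60)
  expect_error(identify_sequence(short, code, "B"), "length")
  expect_warning(res <- identify_sequence(short, code, "B", pad = "trailing-A"),
                 "padding")
  expect_identical(res$status, "codeword")    # all-A maps to the zero word
  long <- strrep("A", 70)
  expect_warning(res2 <- identify_sequence(long, code, "B", truncate = "tail"),
                 "truncating")
  expect_identical(res2$status, "codeword")
})
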