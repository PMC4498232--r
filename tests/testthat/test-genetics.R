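# Genetic-code tables and codon-level annotation of identified changes.

cloud_result <- function(input, generated, position) {
  list(status = "cloud", position = position,
       input_sequence = input, generated_sequence = generated)
}

test_that("every shipped table maps 64 codons; standard has 61 sense + 3 stops", {
  for (name in list_genetic_codes()) {
    tab <- genetic_code_table(name)
    expect_length(tab$codons, 64)
    expect_false(any(is.na(tab$codons)))
  }
  std <- genetic_code_table("standard")$codons
  expect_equal(sum(std == "*"), 3)
  expect_equal(sum(std != "*"), 61)
  expect_setequal(names(std)[std == "*"], c("TAA", "TAG", "TGA"))
})

test_that("deviant tables differ from standard on documented codons only", {
  std <- genetic_code_table("standard")$codons
  reassigned <- list(
    "vertebrate-mito"     = c("TGA", "AGA", "AGG", "ATA"),
    "yeast-mito"          = c("TGA", "ATA", "CTT", "CTC", "CTA", "CTG"),
    "mold-protozoan-mito" = c("TGA"),
    "invertebrate-mito"   = c("TGA", "AGA", "AGG", "ATA"),
    "ciliate-nuclear"     = c("TAA", "TAG"),
    "cys-reassignment"    = c("TGA")
  )
  for (name in names(reassigned)) {
    tab <- genetic_code_table(name)$codons
    diff <- names(std)[std != tab]
    expect_setequal(diff, reassigned[[name]])
    expect_gt(length(diff), 0)
  }
  # the specific reassignments driving the reinterpretation results
  expect_identical(unname(genetic_code_table("vertebrate-mito")$codons["TGA"]), "W")
  expect_identical(unname(genetic_code_table("invertebrate-mito")$codons["AGA"]), "S")
  expect_identical(unname(genetic_code_table("vertebrate-mito")$codons["ATA"]), "M")
  expect_identical(unname(genetic_code_table("cys-reassignment")$codons["TGA"]), "C")
})

test_that("TGG->TGA is Trp->stop under standard, synonymous under mito Trp tables", {
  res <- cloud_result(paste0("TGG", strrep("A", 60)),
                      paste0("TGA", strrep("A", 60)), position = 3)
  ann <- annotate_codon(res)
  expect_true(ann$translatable)
  expect_equal(ann$codon_index, 1)
  expect_identical(ann$before_codon, "TGG")
  expect_identical(ann$after_codon, "TGA")
  expect_identical(ann$aa_standard_before, "W")
  expect_identical(ann$aa_standard_after, "*")
  expect_true(all(c("vertebrate-mito", "yeast-mito", "mold-protozoan-mito",
                    "invertebrate-mito") %in% ann$synonymous_under))
  expect_false("standard" %in% ann$synonymous_under)
  eff <- classify_effect(ann)
  expect_identical(unname(eff["standard"]), "nonsense")
  expect_identical(unname(eff["vertebrate-mito"]), "silent")
})

test_that("AGT->AGA is Ser->Arg under standard, synonymous where AGA = Ser", {
  res <- cloud_result(paste0("AGT", strrep("C", 60)),
                      paste0("AGA", strrep("C", 60)), position = 3)
  ann <- annotate_codon(res)
  expect_identical(ann$aa_standard_before, "S")
  expect_identical(ann$aa_standard_after, "R")
  expect_true("invertebrate-mito" %in% ann$synonymous_under)
  eff <- classify_effect(ann)
  expect_identical(unname(eff["standard"]), "missense")
  expect_identical(unname(eff["invertebrate-mito"]), "silent")
})

test_that("ATG->ATA is Met->Ile under standard, synonymous where ATA = Met", {
  res <- cloud_result(paste0("ATG", strrep("C", 60)),
                      paste0("ATA", strrep("C", 60)), position = 3)
  ann <- annotate_codon(res)
  expect_identical(ann$aa_standard_before, "M")
  expect_identical(ann$aa_standard_after, "I")
  expect_true(all(c("vertebrate-mito", "yeast-mito", "invertebrate-mito")
                  %in% ann$synonymous_under))
  expect_identical(unname(classify_effect(ann)["standard"]), "missense")
})

test_that("TGC->TGA is nonsense under standard, silent under the Cys table", {
  res <- cloud_result(paste0("TGC", strrep("A", 60)),
                      paste0("TGA", strrep("A", 60)), position = 3)
  ann <- annotate_codon(res)
  eff <- classify_effect(ann)
  expect_identical(unname(eff["standard"]), "nonsense")
  expect_identical(unname(eff["cys-reassignment"]), "silent")
  expect_true("cys-reassignment" %in% ann$synonymous_under)
})

test_that("silent under standard iff synonymous_under includes standard", {
  res <- cloud_result(paste0("GCT", strrep("A", 60)),
                      paste0("GCC", strrep("A", 60)), position = 3)
  ann <- annotate_codon(res)
  expect_identical(unname(classify_effect(ann)["standard"]), "silent")
  expect_true("standard" %in% ann$synonymous_under)
})

test_that("frame offsets shift the codon window; incomplete codons are flagged", {
  res <- cloud_result(paste0("A", "TGG", strrep("A", 59)),
                      paste0("A", "TGA", strrep("A", 59)), position = 4)
  ann <- annotate_codon(res, frame_offset = 1)
  expect_identical(ann$before_codon, "TGG")
  expect_identical(ann$after_codon, "TGA")
  # alteration before the frame starts
  res2 <- cloud_result("TACGTA", "AACGTA", position = 1)
  expect_false(annotate_codon(res2, frame_offset = 2)$translatable)
  # alteration in an incomplete trailing codon
  res3 <- cloud_result("ACGTACGA", "ACGTACGT", position = 8)
  ann3 <- annotate_codon(res3, frame_offset = 0)
  expect_false(ann3$translatable)
  expect_error(classify_effect(ann3), "not translatable")
  expect_error(annotate_codon(list(status = "codeword")), "cloud")
})
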