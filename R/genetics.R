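# Codon-level consequences of a code-suggested nucleotide change, under the
# standard genetic code and deviant (noncanonical) codes in which specific
# codons are reassigned -- e.g. TGA read as Trp in most mitochondrial
# codes, AGA as Ser and ATA as Met in invertebrate mitochondria, TGA as
# Cys in the Euplotid nuclear code.

.GENETIC_CODE_IDS <- c(
  "standard"            = "1",
  "vertebrate-mito"     = "2",
  "yeast-mito"          = "3",
  "mold-protozoan-mito" = "4",
  "invertebrate-mito"   = "5",
  "ciliate-nuclear"     = "6",
  "cys-reassignment"    = "10"   # Euplotid nuclear: TGA -> Cys
)

#' Genetic-code tables
#'
#' \code{genetic_code_table} returns one translation table by name;
#' \code{list_genetic_codes} names the shipped tables.  Tables are the
#' NCBI translation tables (via Biostrings): standard (1),
#' vertebrate-mito (2), yeast-mito (3), mold-protozoan-mito (4),
#' invertebrate-mito (5), ciliate-nuclear (6) and cys-reassignment (10,
#' the Euplotid nuclear code in which TGA codes for Cys).
#'
#' @param name table name (see \code{list_genetic_codes()}).
#' @return list with \code{name}, \code{ncbi_id} and \code{codons}, a
#'   named character vector over all 64 codons (stop = \code{"*"}).
#' @export
genetic_code_table <- function(name) {
  if (!name %in% names(.GENETIC_CODE_IDS))
    stop("unknown genetic code '", name, "'; see list_genetic_codes()")
  id <- .GENETIC_CODE_IDS[[name]]
  codons <- Biostrings::getGeneticCode(id)
  list(name = name, ncbi_id = id, codons = codons[1:64])
}

#' @rdname genetic_code_table
#' @export
list_genetic_codes <- function() names(.GENETIC_CODE_IDS)

.translate_codon <- function(codon, table) unname(table$codons[codon])

#' Annotate the codon consequence of an identified alteration
#'
#' For a cloud identification, extracts the codon containing the altered
#' nucleotide from the input and the code-generated sequence (given the
#' reading-frame offset), translates both under every requested table, and
#' computes under which tables the change is synonymous.
#'
#' @param result an \code{sga_identification} with status \code{"cloud"},
#'   or a list with \code{input_sequence}, \code{generated_sequence},
#'   \code{position} (1-based).
#' @param frame_offset 0, 1 or 2: number of nucleotides before the first
#'   complete codon.
#' @param tables character vector of table names (default: all shipped).
#' @return object of class \code{codon_annotation}: list with
#'   \code{translatable}, \code{codon_index} (1-based within frame),
#'   \code{before_codon}, \code{after_codon}, \code{aa_standard_before},
#'   \code{aa_standard_after}, \code{translations} (data.frame: table,
#'   aa_before, aa_after), \code{synonymous_under}.
#' @examples
#' \dontrun{
#' res <- identify_sequence(seq, "3.a")
#' annotate_codon(res, tables = c("standard", "vertebrate-mito"))
#' }
#' @export
annotate_codon <- function(result, frame_offset = 0L,
                           tables = list_genetic_codes()) {
  stopifnot(frame_offset %in% 0:2)
  if (!identical(result$status, "cloud"))
    stop("annotate_codon requires a cloud identification")
  pos <- result$position
  seq_in <- result$input_sequence
  seq_gen <- result$generated_sequence
  base <- list(frame_offset = as.integer(frame_offset),
               position = pos, translatable = FALSE,
               codon_index = NA_integer_, before_codon = NA_character_,
               after_codon = NA_character_,
               aa_standard_before = NA_character_,
               aa_standard_after = NA_character_,
               translations = NULL, synonymous_under = character(0))
  if (pos <= frame_offset) {
    out <- structure(base, class = "codon_annotation")
    return(out)
  }
  ci <- ((pos - frame_offset - 1L) %/% 3L) + 1L
  start <- frame_offset + 3L * (ci - 1L) + 1L
  end <- start + 2L
  if (end > nchar(seq_in)) {      # incomplete trailing codon
    base$codon_index <- ci
    return(structure(base, class = "codon_annotation"))
  }
  before <- substr(seq_in, start, end)
  after <- substr(seq_gen, start, end)
  tabs <- lapply(tables, genetic_code_table)
  aa_before <- vapply(tabs, .translate_codon, character(1), codon = before)
  aa_after <- vapply(tabs, .translate_codon, character(1), codon = after)
  trans <- data.frame(table = tables, aa_before = aa_before,
                      aa_after = aa_after, stringsAsFactors = FALSE)
  std <- match("standard", tables)
  base$translatable <- TRUE
  base$codon_index <- ci
  base$before_codon <- before
  base$after_codon <- after
  if (!is.na(std)) {
    base$aa_standard_before <- aa_before[std]
    base$aa_standard_after <- aa_after[std]
  }
  base$translations <- trans
  base$synonymous_under <- tables[aa_before == aa_after]
  structure(base, class = "codon_annotation")
}

#' @export
print.codon_annotation <- function(x, ...) {
  if (!x$translatable) {
    cat("codon annotation: not translatable (position ", x$position,
        ", frame offset ", x$frame_offset, ")\n", sep = "")
    return(invisible(x))
  }
  cat("codon ", x$codon_index, ": ", x$before_codon, " -> ", x$after_codon,
      " (standard: ", x$aa_standard_before, " -> ", x$aa_standard_after,
      ")\n", sep = "")
  if (length(x$synonymous_under))
    cat("  synonymous under: ", paste(x$synonymous_under, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Classify the per-table effect of an annotated change
#'
#' @param annotation a translatable \code{codon_annotation}.
#' @return named character vector over the annotation's tables with values
#'   \code{"silent"}, \code{"missense"}, \code{"nonsense"} or
#'   \code{"stop_loss"}.
#' @export
classify_effect <- function(annotation) {
  stopifnot(inherits(annotation, "codon_annotation"))
  if (!annotation$translatable)
    stop("annotation is not translatable")
  tr <- annotation$translations
  eff <- ifelse(tr$aa_before == tr$aa_after, "silent",
         ifelse(tr$aa_after == "*", "nonsense",
         ifelse(tr$aa_before == "*", "stop_loss", "missense")))
  stats::setNames(eff, tr$table)
}
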