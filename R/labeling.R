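# Nucleotide labelings: bijections {A,C,G,T} <-> the four code symbols
# (Z4 = {0,1,2,3}; for field codes the same integers are read in the GF(4)
# encoding 0,1,a,b).  The named defaults A-D are a fixed convention of this
# package (user-overridable); see the methods vignette.

.DEFAULT_LABELINGS <- list(
  A = c(A = 0L, C = 1L, G = 2L, T = 3L),
  B = c(A = 0L, C = 1L, G = 3L, T = 2L),
  C = c(A = 0L, C = 2L, G = 1L, T = 3L),
  D = c(A = 0L, C = 2L, G = 3L, T = 1L)
)

#' Nucleotide labelings
#'
#' \code{sga_labeling} returns one labeling by name (one of the built-in
#' \code{"A"}--\code{"D"}) or builds a custom labeling from a named
#' integer vector; \code{sga_labelings} lists the four built-ins.
#'
#' @param name labeling name.
#' @param mapping named integer vector mapping \code{c(A=,C=,G=,T=)} to a
#'   permutation of 0:3; ignored when \code{name} is a built-in.
#' @return an object of class \code{sga_labeling}: list with \code{name},
#'   \code{map} (named integer vector) and \code{inverse} (character
#'   vector indexed by symbol + 1).
#' @examples
#' sga_labeling("C")
#' @export
sga_labeling <- function(name, mapping = NULL) {
  if (is.null(mapping)) {
    if (!name %in% names(.DEFAULT_LABELINGS))
      stop("unknown labeling '", name, "'; built-ins are A, B, C, D")
    mapping <- .DEFAULT_LABELINGS[[name]]
  } else {
    mapping <- as.integer(mapping[c("A", "C", "G", "T")])
    names(mapping) <- c("A", "C", "G", "T")
    if (any(is.na(mapping)) || !setequal(mapping, 0:3))
      stop("mapping must assign A,C,G,T a permutation of 0:3")
  }
  inverse <- character(4)
  inverse[mapping + 1L] <- names(mapping)
  structure(list(name = name, map = mapping, inverse = inverse),
            class = "sga_labeling")
}

#' @rdname sga_labeling
#' @export
sga_labelings <- function() lapply(names(.DEFAULT_LABELINGS), sga_labeling)

#' @export
print.sga_labeling <- function(x, ...) {
  cat("labeling ", x$name, ": ",
      paste(names(x$map), x$map, sep = "->", collapse = ", "), "\n", sep = "")
  invisible(x)
}

.validate_dna <- function(seq, id = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("record '", id, "' contains non-ACGT characters at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "")
  chars
}

#' Map a DNA sequence to code symbols
#'
#' Per-position substitution of nucleotides by code symbols through the
#' labeling bijection, preserving order (position 1 of the symbol vector is
#' the leftmost nucleotide and carries the highest polynomial degree).
#'
#' @param seq a DNA string over A,C,G,T (case-insensitive).
#' @param labeling an \code{sga_labeling} or a built-in labeling name.
#' @return integer symbol vector.
#' @export
apply_labeling <- function(seq, labeling) {
  if (is.character(labeling)) labeling <- sga_labeling(labeling)
  stopifnot(inherits(labeling, "sga_labeling"))
  chars <- .validate_dna(seq)
  unname(labeling$map[chars])
}

#' Map code symbols back to a DNA sequence
#'
#' Inverse of \code{\link{apply_labeling}}.
#'
#' @param symbols integer vector over 0:3.
#' @param labeling an \code{sga_labeling} or a built-in labeling name.
#' @return a DNA string.
#' @export
invert_labeling <- function(symbols, labeling) {
  if (is.character(labeling)) labeling <- sga_labeling(labeling)
  stopifnot(inherits(labeling, "sga_labeling"))
  symbols <- as.integer(symbols)
  if (any(symbols < 0L | symbols > 3L)) stop("symbols must be in 0..3")
  paste(labeling$inverse[symbols + 1L], collapse = "")
}
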