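# Identification of DNA sequences against a code: a sequence either is the
# image of a codeword ("codeword"), lies at nucleotide Hamming distance
# exactly 1 from one ("cloud" -- the code then proposes the original base),
# or is farther away ("unidentified").

#' Identify a DNA sequence against a code
#'
#' Maps the sequence to code symbols through the labeling, runs the
#' single-error syndrome decoder, and maps any corrected codeword back to
#' nucleotides (the code-generated sequence).  A cloud verdict reports the
#' altered 1-based position together with the original and the
#' code-suggested nucleotide; the generated sequence then differs from the
#' input at exactly that position.
#'
#' @param seq a DNA string of length n (the code length), or a length-1
#'   named character vector (the name is used as the sequence id).
#' @param code an \code{sga_code} or a preset key.
#' @param labeling an \code{sga_labeling} or labeling name; defaults to
#'   the preset's labeling when the code carries one.
#' @param id sequence identifier for reporting.
#' @param pad \code{"none"} (default: strict length equality) or
#'   \code{"trailing-A"}: pad a short sequence with A up to n (logged
#'   loudly via a warning).
#' @param truncate \code{"none"} or \code{"tail"}: drop trailing
#'   nucleotides of a long sequence down to n (warned).
#' @return an object of class \code{sga_identification}: list with
#'   \code{seq_id}, \code{code_key}, \code{labeling}, \code{status}
#'   (\code{"codeword"}, \code{"cloud"} or \code{"unidentified"}),
#'   \code{position} (1-based nucleotide coordinate, cloud only),
#'   \code{original_nt}, \code{suggested_nt}, \code{generated_sequence}
#'   and \code{input_sequence}.
#' @examples
#' code <- build_code("S02.b")
#' lab <- sga_labeling("B")
#' cw <- encode(rep(0L, code$k), code)
#' identify_sequence(invert_labeling(cw, lab), code, lab)
#' @export
identify_sequence <- function(seq, code, labeling = NULL, id = NULL,
                              pad = c("none", "trailing-A"),
                              truncate = c("none", "tail")) {
  pad <- match.arg(pad)
  truncate <- match.arg(truncate)
  if (is.character(code)) code <- build_code(code)
  stopifnot(inherits(code, "sga_code"))
  if (is.null(labeling)) {
    if (is.na(code$default_labeling))
      stop("no labeling given and the code carries no default")
    labeling <- code$default_labeling
  }
  if (is.character(labeling)) labeling <- sga_labeling(labeling)
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  seq <- toupper(unname(seq)[1])
  if (nchar(seq) < code$n && pad == "trailing-A") {
    warning("padding '", id, "' with ", code$n - nchar(seq),
            " trailing A to length n = ", code$n, call. = FALSE)
    seq <- paste0(seq, strrep("A", code$n - nchar(seq)))
  }
  if (nchar(seq) > code$n && truncate == "tail") {
    warning("truncating '", id, "' from ", nchar(seq), " to n = ", code$n,
            " nt", call. = FALSE)
    seq <- substr(seq, 1L, code$n)
  }
  if (nchar(seq) != code$n)
    stop("sequence '", id, "' has length ", nchar(seq),
         " but the code length is n = ", code$n)
  r <- apply_labeling(seq, labeling)
  out <- decode_single_error(r, code)
  res <- list(seq_id = id, code_key = code$key, labeling = labeling$name,
              status = NA_character_, position = NA_integer_,
              original_nt = NA_character_, suggested_nt = NA_character_,
              generated_sequence = NA_character_, input_sequence = seq)
  if (out$status == "no_error") {
    res$status <- "codeword"
    res$generated_sequence <- seq
  } else if (out$status == "corrected") {
    res$status <- "cloud"
    res$position <- out$position
    gen <- invert_labeling(out$corrected_vector, labeling)
    res$generated_sequence <- gen
    res$original_nt <- substr(seq, out$position, out$position)
    res$suggested_nt <- substr(gen, out$position, out$position)
  } else {
    res$status <- "unidentified"
  }
  structure(res, class = "sga_identification")
}

#' @export
print.sga_identification <- function(x, ...) {
  cat("identification of '", x$seq_id, "' against [", x$code_key,
      "] with labeling ", x$labeling, ": ", x$status, "\n", sep = "")
  if (identical(x$status, "cloud"))
    cat("  position ", x$position, " (1-based): ", x$original_nt, " -> ",
        x$suggested_nt, "\n", sep = "")
  invisible(x)
}

#' Scan a sequence against many presets
#'
#' Runs \code{\link{identify_sequence}} for every (code, labeling) pair
#' whose code length matches the sequence; length-incompatible presets
#' yield an explicit \code{"skipped"} row.  Results are ordered by
#' (code key, labeling name).
#'
#' @param seq a DNA string (optionally named for the id).
#' @param keys preset keys (default: the full registry).
#' @param labelings labeling names to try per code; default: each preset's
#'   own labeling.
#' @param id sequence identifier.
#' @return a data.frame with columns \code{seq_id}, \code{code_key},
#'   \code{labeling}, \code{status}, \code{position_1based}, \code{ref_nt},
#'   \code{alt_nt}, \code{generated_sequence}.
#' @export
scan_sequence <- function(seq, keys = code_registry()$key, labelings = NULL,
                          id = NULL) {
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  seq <- toupper(unname(seq)[1])
  keys <- sort(unique(keys))
  rows <- list()
  for (key in keys) {
    code <- suppressWarnings(build_code(key))
    labs <- if (is.null(labelings)) code$default_labeling else sort(labelings)
    for (lab in labs) {
      if (nchar(seq) != code$n) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = id, code_key = key, labeling = lab, status = "skipped",
          position_1based = NA_integer_, ref_nt = NA_character_,
          alt_nt = NA_character_, generated_sequence = NA_character_,
          stringsAsFactors = FALSE)
        next
      }
      r <- identify_sequence(seq, code, lab, id = id)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, code_key = key, labeling = lab, status = r$status,
        position_1based = r$position, ref_nt = r$original_nt,
        alt_nt = r$suggested_nt, generated_sequence = r$generated_sequence,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), code_key = character(0),
                      labeling = character(0), status = character(0),
                      position_1based = integer(0), ref_nt = character(0),
                      alt_nt = character(0),
                      generated_sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
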