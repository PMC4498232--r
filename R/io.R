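# FASTA input, TSV/JSON reports, YAML run configs and the seeded synthetic
# fixture generator that makes the package testable with no downloads.

#' Read a FASTA file of DNA sequences
#'
#' Parses multi-record FASTA (wrapped or unwrapped lines), uppercases and
#' validates the alphabet: only A, C, G, T are accepted, and offending
#' positions are reported.  Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) .validate_dna(seqs[[i]], ids[i])
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Generate synthetic identification fixtures
#'
#' Draws random length-k messages, encodes them into codewords, maps them
#' to DNA through the labeling, and injects the requested number of random
#' single-nucleotide substitutions at recorded positions.  With
#' \code{errors = 1} every record must identify as cloud with exactly the
#' planted position and reference base; with \code{errors = 0} every
#' record is a codeword image.  Generation is reproducible given
#' (arguments, seed).
#'
#' @param code an \code{sga_code} or preset key.
#' @param labeling an \code{sga_labeling} or name; default the preset's.
#' @param n_seq number of records.
#' @param errors substitutions per record (0, 1 or 2).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param prefix id prefix.
#' @return list with \code{sequences} (named character vector) and
#'   \code{truth} (data.frame: seq_id, planted_position, ref, alt --
#'   one row per planted substitution; \code{ref} is the codeword base the
#'   identifier should restore, \code{alt} the injected base).
#' @export
generate_fixtures <- function(code, labeling = NULL, n_seq = 10L,
                              errors = 1L, seed = NULL, prefix = "fix") {
  if (is.character(code)) code <- build_code(code)
  stopifnot(inherits(code, "sga_code"), errors %in% 0:2)
  if (is.null(labeling)) labeling <- code$default_labeling
  if (is.character(labeling)) labeling <- sga_labeling(labeling)
  if (!is.null(seed)) set.seed(as.integer(seed))
  seqs <- character(n_seq)
  ids <- sprintf("%s_%04d", prefix, seq_len(n_seq))
  truth <- list()
  for (i in seq_len(n_seq)) {
    msg <- sample(0:3, code$k, replace = TRUE)
    cw <- encode(msg, code)
    dna <- invert_labeling(cw, labeling)
    if (errors > 0L) {
      pos <- sample.int(code$n, errors)
      for (p in pos) {
        ref <- substr(dna, p, p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        substr(dna, p, p) <- alt
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = ids[i], planted_position = p, ref = ref, alt = alt,
          stringsAsFactors = FALSE)
      }
    }
    seqs[i] <- dna
  }
  names(seqs) <- ids
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(seq_id = character(0),
                           planted_position = integer(0),
                           ref = character(0), alt = character(0),
                           stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth)
}

#' Write an identification report
#'
#' TSV dialect: tab-separated with a header row, \code{"."} for
#' not-applicable fields, leading \code{#} comment lines recording the run
#' parameters.  JSON mirrors the columns as keys.
#'
#' @param results data.frame as returned by \code{\link{scan_sequence}}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param params optional named list logged in the header.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json"),
                         params = list()) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dnasga identification report (positions are 1-based)", con)
  for (nm in names(params))
    writeLines(paste0("# ", nm, ": ", params[[nm]]), con)
  out <- results
  for (j in seq_along(out)) {
    v <- as.character(out[[j]])
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Resolves a run configuration to concrete objects before any
#' computation: known keys are \code{input}, \code{code} (preset key),
#' \code{labeling}, \code{frame_offset}, \code{pad}, \code{truncate},
#' \code{out}, \code{format}, \code{seed}.  Command-line flags are meant
#' to override config keys (see the \code{inst/cli} script).
#'
#' @param path path to a YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  known <- c("input", "code", "labeling", "frame_offset", "pad",
             "truncate", "out", "format", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  cfg
}
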