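#' The twenty standard amino-acid one-letter codes
#'
#' Residue-class conventions used throughout the package. The hydrophobic set
#' {A, V, L, I, M, F, W} deliberately excludes C, G, Y and P; histidine is
#' counted as positively charged alongside R and K. Under these conventions
#' the reference peptide Pep-MD (YRGWHCRGITKNGIIFDIKW) contains seven
#' hydrophobic, five positively charged and one negatively charged residue.
#'
#' @name residue-classes
#' @keywords internal
NULL

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W")
AA_POSITIVE <- c("R", "K", "H")
AA_NEGATIVE <- c("D", "E")

#' Reference peptide Pep-MD
#'
#' The top-ranked 20-mer candidate used as the worked example across the
#' package: `YRGWHCRGITKNGIIFDIKW`.
#'
#' @return A length-one [peptides] object named `"Pep-MD"`.
#' @export
#' @examples
#' classify_residues(pep_md())
pep_md <- function() peptides("YRGWHCRGITKNGIIFDIKW", ids = "Pep-MD")

#' Construct a validated set of peptide sequences
#'
#' A `peptide_set` is a named character vector of residue strings over the
#' 20-letter amino-acid alphabet; the names are the sequence ids. Lowercase
#' input is upcased. Any non-standard letter (B, J, O, U, X, Z, symbols)
#' is rejected with an error naming the offending record and character.
#'
#' @param residues character vector of residue strings.
#' @param ids character vector of ids (defaults to names of `residues`, or
#'   `seq1`, `seq2`, ... when unnamed).
#' @return A `peptide_set` object.
#' @export
#' @examples
#' p <- peptides(c(tat = "GRKKRRQRRR"))
#' nchar(p)
peptides <- function(residues, ids = NULL) {
  if (length(residues) == 0L) {
    x <- character(0)
    class(x) <- c("peptide_set", "character")
    return(x)
  }
  if (is.null(ids)) {
    ids <- names(residues)
    if (is.null(ids)) ids <- paste0("seq", seq_along(residues))
  }
  if (length(ids) != length(residues)) {
    stop_validation("`ids` and `residues` lengths differ")
  }
  residues <- toupper(as.character(residues))
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    if (is.na(r) || !nzchar(r)) {
      stop_validation("record '", ids[[i]], "': empty sequence")
    }
    letters_i <- strsplit(r, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(letters_i), AA_STANDARD)
    if (length(bad) > 0L) {
      stop_validation("record '", ids[[i]], "': non-standard residue '",
                      bad[[1]], "'")
    }
  }
  x <- residues
  names(x) <- ids
  class(x) <- c("peptide_set", "character")
  x
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("peptide_set of", length(x), "sequence(s)\n")
  n <- min(length(x), 10L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-20s %s (%d aa)\n", names(x)[i], x[[i]], nchar(x[[i]])))
  }
  if (length(x) > n) cat("  ...", length(x) - n, "more\n")
  invisible(x)
}

#' @export
`[.peptide_set` <- function(x, i, ...) {
  y <- NextMethod()
  class(y) <- c("peptide_set", "character")
  y
}

#' Read peptide sequences from a FASTA file
#'
#' Multi-line record bodies are concatenated and lowercase letters upcased.
#' Records containing any non-standard residue letter are rejected with an
#' error naming the record and the character.
#'
#' @param path path to a FASTA file.
#' @return A [peptides] object, one element per record in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  if (file.size(path) == 0L) return(peptides(character(0)))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop_io("failed to parse FASTA '", path, "': ",
                                conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(seqs))
  peptides(as.character(seqs), ids = ids)
}

#' Write peptide sequences to a FASTA file
#'
#' Writes standard FASTA with `>id` headers and sequence bodies wrapped at
#' 60 columns. Round-trips with [read_fasta()].
#'
#' @param x a [peptides] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (length(x) > 0L && is.null(names(x))) {
    stop_validation("peptide set must be named")
  }
  set <- Biostrings::BStringSet(unclass(x))
  ok <- tryCatch({
    Biostrings::writeXStringSet(set, filepath = path, width = 60L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write FASTA to '", path, "'")
  invisible(path)
}

#' Classify residues of a peptide by physicochemical class
#'
#' Hydrophobic = {A, V, L, I, M, F, W}; positively charged = {R, K, H};
#' negatively charged = {D, E}; everything else is unclassified. The three
#' position lists are disjoint and their counts plus the unclassified count
#' sum to the sequence length.
#'
#' @param seq a single residue string or a length-one [peptides] object.
#' @return An object of class `residue_classes` with 1-based position lists
#'   and per-class counts.
#' @export
#' @examples
#' classify_residues("YRGWHCRGITKNGIIFDIKW")
classify_residues <- function(seq) {
  seq <- as_single_peptide(seq)
  letters_i <- strsplit(unclass(seq)[[1]], "", fixed = TRUE)[[1]]
  hyd <- which(letters_i %in% AA_HYDROPHOBIC)
  pos <- which(letters_i %in% AA_POSITIVE)
  neg <- which(letters_i %in% AA_NEGATIVE)
  structure(list(
    id = names(seq),
    residues = unclass(seq)[[1]],
    length = length(letters_i),
    hydrophobic_positions = hyd,
    positive_positions = pos,
    negative_positions = neg,
    n_hydrophobic = length(hyd),
    n_positive = length(pos),
    n_negative = length(neg),
    n_unclassified = length(letters_i) - length(hyd) - length(pos) - length(neg)
  ), class = "residue_classes")
}

#' @export
print.residue_classes <- function(x, ...) {
  cat(sprintf("%s (%d aa): %d hydrophobic, %d positive, %d negative, %d other\n",
              x$id, x$length, x$n_hydrophobic, x$n_positive, x$n_negative,
              x$n_unclassified))
  invisible(x)
}

#' Charged residue positions of a peptide
#'
#' Union of positively and negatively charged positions, ascending, labelled
#' residue-letter + 1-based position (e.g. `R2`, `D17`).
#'
#' @inheritParams classify_residues
#' @return A data frame with columns `residue`, `position`, `label`.
#' @export
#' @examples
#' charged_positions("YRGWHCRGITKNGIIFDIKW")$label
charged_positions <- function(seq) {
  cls <- classify_residues(seq)
  pos <- sort(c(cls$positive_positions, cls$negative_positions))
  letters_i <- strsplit(cls$residues, "", fixed = TRUE)[[1]]
  data.frame(
    residue = if (length(pos)) letters_i[pos] else character(0),
    position = as.integer(pos),
    label = if (length(pos)) paste0(letters_i[pos], pos) else character(0),
    stringsAsFactors = FALSE
  )
}

#' Composition-preserving shuffle of a peptide sequence
#'
#' Draws a uniform random permutation of the residue letters (Fisher-Yates
#' via `sample.int`) under an explicit seed; the output id records the seed
#' for provenance. The residue multiset is always preserved.
#'
#' @inheritParams classify_residues
#' @param seed integer seed controlling the permutation.
#' @return A length-one [peptides] object with id `<id>_shuf<seed>`.
#' @export
shuffle_sequence <- function(seq, seed) {
  seq <- as_single_peptide(seq)
  letters_i <- strsplit(unclass(seq)[[1]], "", fixed = TRUE)[[1]]
  perm <- with_seed(seed, sample.int(length(letters_i)))
  peptides(paste(letters_i[perm], collapse = ""),
           ids = paste0(names(seq), "_shuf", seed))
}

#' Residue-class report for a set of peptides
#'
#' One row per peptide: id, length, class counts and the charged-position
#' labels, optionally written as TSV.
#'
#' @param x a [peptides] object.
#' @param path optional output TSV path.
#' @return A data frame (invisibly written to `path` when given).
#' @export
residue_report <- function(x, path = NULL) {
  rows <- lapply(seq_along(x), function(i) {
    cls <- classify_residues(x[i])
    data.frame(
      id = names(x)[i], length = cls$length,
      n_hydrophobic = cls$n_hydrophobic, n_positive = cls$n_positive,
      n_negative = cls$n_negative,
      charged_position_labels = paste(charged_positions(x[i])$label,
                                      collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# Coerce a residue string or length-one peptide_set to a named length-one
# peptide_set.
as_single_peptide <- function(seq) {
  if (inherits(seq, "peptide_set")) {
    if (length(seq) != 1L) stop_validation("expected a single peptide")
    return(seq)
  }
  if (is.character(seq) && length(seq) == 1L) {
    id <- names(seq)
    if (is.null(id)) id <- "seq1"
    return(peptides(seq, ids = id))
  }
  stop_validation("expected a residue string or a length-one peptide_set")
}
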