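# Training-set redundancy removal and the rule-based synthesizability
# filter applied to generated candidates.

#' Remove redundant sequences by pairwise alignment identity
#'
#' Greedy first-representative clustering: sequences are scanned in input
#' order; a sequence whose global-alignment identity (identical positions /
#' alignment length) against any already-kept representative reaches the
#' cutoff is dropped. Alignments are computed with BLOSUM62 and affine gaps
#' through `Biostrings::pairwiseAlignment`.
#'
#' @param sequences a [peptides] object.
#' @param cutoff identity cutoff in (0, 1] (default 0.35).
#' @return A [peptides] object of cluster representatives, input order
#'   preserved.
#' @export
deduplicate_training <- function(sequences, cutoff = 0.35) {
  if (cutoff <= 0 || cutoff > 1) stop_validation("cutoff must be in (0, 1]")
  if (length(sequences) <= 1L) return(sequences)
  mat <- blosum62()
  keep <- logical(length(sequences))
  reps <- Biostrings::AAStringSet(character(0))
  for (i in seq_along(sequences)) {
    s <- unclass(sequences)[[i]]
    if (length(reps) == 0L) {
      keep[i] <- TRUE
      reps <- Biostrings::AAStringSet(s)
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = reps, subject = s, type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1)
    aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ident <- Biostrings::nmatch(aln) / aln_len
    if (max(ident) < cutoff) {
      keep[i] <- TRUE
      reps <- c(reps, Biostrings::AAStringSet(s))
    }
  }
  sequences[keep]
}

#' Rule-based synthesizability score
#'
#' A documented stand-in for external synthesizability services, on a 0-5
#' scale. Starting from 5, penalties are applied for motifs known to be
#' difficult in solid-phase synthesis: long hydrophobic runs (>= 5
#' consecutive residues of {A,V,L,I,M,F,W}: -2), multiple cysteines (-1 per
#' cysteine beyond the first, capped at -2), and length over 30 (-1). The
#' result is floored at 0.
#'
#' @inheritParams classify_residues
#' @return A numeric score in `[0, 5]`.
#' @export
default_synthesizability <- function(seq) {
  s <- as_residue_string(seq)
  letters_i <- strsplit(s, "", fixed = TRUE)[[1]]
  runs <- rle(letters_i %in% AA_HYDROPHOBIC)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  n_cys <- sum(letters_i == "C")
  score <- 5
  if (max_run >= 5L) score <- score - 2
  score <- score - min(2, max(0, n_cys - 1))
  if (length(letters_i) > 30L) score <- score - 1
  max(score, 0)
}

#' Filter peptides by synthesizability
#'
#' Keeps sequences whose score under `scorer` is at least `threshold`,
#' preserving input order. A scorer failure is reported with the offending
#' sequence id.
#'
#' @param sequences a [peptides] object.
#' @param scorer function mapping one sequence to a numeric score (default
#'   [default_synthesizability()]).
#' @param threshold minimum score kept (default 3).
#' @return The retained [peptides].
#' @export
filter_synthesizable <- function(sequences, scorer = default_synthesizability,
                                 threshold = 3) {
  scores <- vapply(seq_along(sequences), function(i) {
    val <- tryCatch(scorer(sequences[i]), error = function(e) {
      stop_validation("synthesizability scorer failed on '",
                      names(sequences)[i], "': ", conditionMessage(e))
    })
    if (!is.numeric(val) || length(val) != 1L || is.na(val)) {
      stop_validation("synthesizability scorer returned a non-numeric ",
                      "score for '", names(sequences)[i], "'")
    }
    val
  }, 0)
  sequences[scores >= threshold]
}
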