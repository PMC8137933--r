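# Shuffled-sequence null analysis: composition-preserving permutation
# ensembles, force-group splitting, per-column alignment profiles
# (consensus / occupancy / quality), motif extraction and charged-position
# comparison against the consensus.

#' Null-analysis configuration
#'
#' @param n_shuffles number of composition-preserving shuffles (default 100).
#' @param high_threshold forces strictly above this (kJ mol^-1 nm^-1) fall in
#'   the high group (default 720).
#' @param low_threshold forces strictly below this fall in the low group
#'   (default 680).
#' @param seed master seed for the ensemble.
#' @param unique require all shuffles to be pairwise distinct (default FALSE).
#' @return A list of class `null_config`.
#' @export
null_config <- function(n_shuffles = 100L, high_threshold = 720,
                        low_threshold = 680, seed = 1L, unique = FALSE) {
  if (n_shuffles < 1L) stop_validation("n_shuffles must be >= 1")
  if (low_threshold > high_threshold) {
    stop_validation("low_threshold must be <= high_threshold")
  }
  structure(list(n_shuffles = as.integer(n_shuffles),
                 high_threshold = high_threshold,
                 low_threshold = low_threshold,
                 seed = as.integer(seed), unique = isTRUE(unique)),
            class = "null_config")
}

#' Generate a composition-preserving shuffle ensemble
#'
#' Draws `n_shuffles` random permutations of the peptide, each via
#' [shuffle_sequence()] with a per-shuffle seed derived from the config
#' seed, so the ensemble is reproducible and individual members can be
#' regenerated in isolation. With `unique = TRUE`, duplicate draws are
#' rejected and redrawn; this errors when the residue multiset admits
#' fewer distinct permutations than requested.
#'
#' @inheritParams classify_residues
#' @param config a [null_config()].
#' @return A [peptides] object of `n_shuffles` sequences.
#' @export
generate_null_ensemble <- function(seq, config = null_config()) {
  seq <- as_single_peptide(seq)
  letters_i <- strsplit(unclass(seq)[[1]], "", fixed = TRUE)[[1]]
  if (config$unique) {
    counts <- table(letters_i)
    n_distinct <- exp(lgamma(length(letters_i) + 1) - sum(lgamma(counts + 1)))
    if (n_distinct < config$n_shuffles) {
      stop_validation("only ", round(n_distinct),
                      " distinct permutations exist; cannot draw ",
                      config$n_shuffles, " unique shuffles")
    }
  }
  out <- character(config$n_shuffles)
  ids <- character(config$n_shuffles)
  seen <- character(0)
  for (i in seq_len(config$n_shuffles)) {
    attempt <- 0L
    repeat {
      s <- derive_seed(config$seed, "shuffle", i, attempt)
      sh <- shuffle_sequence(seq, s)
      if (!config$unique || !(unclass(sh)[[1]] %in% seen)) break
      attempt <- attempt + 1L
      if (attempt > 10000L) stop_validation("could not draw a unique shuffle")
    }
    out[i] <- unclass(sh)[[1]]
    ids[i] <- paste0(names(seq), "_shuf", sprintf("%03d", i))
    seen <- c(seen, out[i])
  }
  peptides(out, ids = ids)
}

#' Split peptides into high / low / intermediate force groups
#'
#' Strict comparisons: high when force > `high_threshold`, low when force <
#' `low_threshold`, intermediate otherwise (boundary values are
#' intermediate). The three groups partition the input.
#'
#' @param forces named numeric vector of maximum steering forces
#'   (kJ mol^-1 nm^-1), names = peptide ids.
#' @param config a [null_config()] carrying the thresholds.
#' @return A list of class `force_group_split` with id vectors `high`,
#'   `low`, `intermediate`.
#' @export
split_force_groups <- function(forces, config = null_config()) {
  if (length(forces) > 0L && is.null(names(forces))) {
    stop_validation("`forces` must be named by peptide id")
  }
  if (any(!is.finite(unlist(forces)))) stop_validation("forces must be finite")
  ids <- names(forces)
  structure(list(
    high = ids[forces > config$high_threshold],
    low = ids[forces < config$low_threshold],
    intermediate = ids[forces >= config$low_threshold &
                         forces <= config$high_threshold]
  ), class = "force_group_split")
}

#' @export
print.force_group_split <- function(x, ...) {
  cat(sprintf("force groups: %d high, %d low, %d intermediate\n",
              length(x$high), length(x$low), length(x$intermediate)))
  invisible(x)
}

#' Per-column consensus / occupancy / quality profile of an alignment
#'
#' For every column: consensus = modal non-gap residue (alphabetical on
#' ties); consensus fraction = modal count / number of rows; occupancy =
#' non-gap rows / rows; quality = mean pairwise substitution score among the
#' non-gap residues, scaled to `[0, 1]` between the matrix minimum and the
#' largest self-score among the residues present, so that a perfectly
#' conserved column scores 1 regardless of which residue it carries.
#' Columns with fewer than two non-gap residues have quality 1 (vacuous
#' agreement).
#'
#' @param msa a `peptide_msa` from [star_msa()] (or any character matrix of
#'   single letters with `-` gaps).
#' @param matrix substitution matrix (default [blosum62()]).
#' @return A data frame of class `alignment_profile`, one row per column:
#'   `column`, `consensus`, `consensus_fraction`, `occupancy`, `quality`.
#' @export
profile_stats <- function(msa, matrix = blosum62()) {
  nr <- nrow(msa); nc <- ncol(msa)
  out <- data.frame(column = seq_len(nc), consensus = NA_character_,
                    consensus_fraction = 0, occupancy = 0, quality = 1,
                    stringsAsFactors = FALSE)
  mat_min <- min(matrix)
  for (j in seq_len(nc)) {
    col <- msa[, j]
    res <- col[col != "-"]
    out$occupancy[j] <- length(res) / nr
    if (length(res) == 0L) {
      out$consensus[j] <- "-"
      next
    }
    tab <- table(res)
    top <- max(tab)
    out$consensus[j] <- sort(names(tab)[tab == top])[1]
    out$consensus_fraction[j] <- top / nr
    if (length(res) >= 2L) {
      pairs <- utils::combn(length(res), 2L)
      scores <- matrix[cbind(res[pairs[1, ]], res[pairs[2, ]])]
      qmax <- max(diag(matrix[res, res, drop = FALSE]))
      q <- (mean(scores) - mat_min) / (qmax - mat_min)
      out$quality[j] <- min(max(q, 0), 1)
    }
  }
  class(out) <- c("alignment_profile", "data.frame")
  out
}

#' Extract high-consensus, high-occupancy motifs from a profile
#'
#' Scans for maximal runs of columns whose consensus fraction and occupancy
#' both meet the thresholds. A single interior sub-threshold column may be
#' bridged and is rendered as `-` in the pattern (permitting patterns such
#' as `WII-G`). Runs spanning fewer than `min_len` columns are dropped.
#'
#' @param profile an `alignment_profile` from [profile_stats()].
#' @param min_consensus minimum consensus fraction, in (0, 1].
#' @param min_occupancy minimum occupancy, in (0, 1].
#' @param min_len minimum motif span in columns (default 2).
#' @return A data frame of class `motif_set` with columns `pattern`,
#'   `start`, `length`.
#' @export
extract_motifs <- function(profile, min_consensus = 0.5, min_occupancy = 0.5,
                           min_len = 2L) {
  if (min_consensus <= 0 || min_consensus > 1 ||
      min_occupancy <= 0 || min_occupancy > 1) {
    stop_validation("thresholds must lie in (0, 1]")
  }
  pass <- profile$consensus_fraction >= min_consensus &
    profile$occupancy >= min_occupancy
  n <- length(pass)
  motifs <- list()
  j <- 1L
  while (j <= n) {
    if (!pass[j]) { j <- j + 1L; next }
    # grow a run from j, allowing isolated single sub-threshold columns
    end <- j
    k <- j + 1L
    while (k <= n) {
      if (pass[k]) {
        end <- k; k <- k + 1L
      } else if (k + 1L <= n && pass[k + 1L]) {
        k <- k + 1L  # bridge one interior sub-threshold column
      } else break
    }
    span <- end - j + 1L
    if (span >= min_len) {
      letters_run <- ifelse(pass[j:end], profile$consensus[j:end], "-")
      motifs[[length(motifs) + 1L]] <- data.frame(
        pattern = paste(letters_run, collapse = ""),
        start = j, length = span, stringsAsFactors = FALSE)
    }
    j <- end + 1L
  }
  out <- if (length(motifs)) do.call(rbind, motifs) else
    data.frame(pattern = character(0), start = integer(0),
               length = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("motif_set", "data.frame")
  out
}

#' Compare charged positions of a peptide with profile consensus charges
#'
#' For every charged residue of `seq` (positions taken as alignment columns;
#' the sequence must be alignable to the profile width, e.g. the unshuffled
#' reference against a profile of its own shuffles), reports whether some
#' column within `window` columns has a charged consensus residue
#' (R, K, H, D or E).
#'
#' @inheritParams classify_residues
#' @param profile an `alignment_profile`.
#' @param window maximum column distance for a match (default 1).
#' @return A data frame with one row per charged position: `label`,
#'   `position`, `matched`, `nearest_consensus_column` (NA when unmatched),
#'   plus attributes `n_matched` / `n_unmatched`.
#' @export
compare_charged_positions <- function(seq, profile, window = 1L) {
  chg <- charged_positions(seq)
  charged_cols <- profile$column[profile$consensus %in%
                                   c(AA_POSITIVE, AA_NEGATIVE)]
  rows <- lapply(seq_len(nrow(chg)), function(i) {
    p <- chg$position[i]
    if (length(charged_cols) > 0L) {
      d <- abs(charged_cols - p)
      nearest <- charged_cols[which.min(d)]
      matched <- min(d) <= window
    } else {
      nearest <- NA_integer_; matched <- FALSE
    }
    data.frame(label = chg$label[i], position = p, matched = matched,
               nearest_consensus_column = if (matched) nearest else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), position = integer(0),
               matched = logical(0), nearest_consensus_column = integer(0),
               stringsAsFactors = FALSE)
  attr(out, "n_matched") <- sum(out$matched)
  attr(out, "n_unmatched") <- sum(!out$matched)
  out
}
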