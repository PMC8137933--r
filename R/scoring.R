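# Sample-variance-penalization scoring of replica maximum steering forces
# and peptide ranking. The mechanistic score of a peptide with replica mean
# m, sample variance v (n - 1 denominator) and replica count n is
#   score = m + lambda * sqrt(v / n)
# with trade-off lambda = 2.5 by default; LOWER is better, and consistency
# across replicas is rewarded.

#' Mechanistic score from summary statistics
#'
#' @param m mean of the replica maximum steering forces (kJ mol^-1 nm^-1).
#' @param sd standard deviation of the replica maxima (>= 0).
#' @param n replica count (>= 1).
#' @param lambda variance-penalization trade-off (default 2.5).
#' @param peptide optional peptide id carried through to reports.
#' @return An object of class `mech_score` with fields `m`, `v`, `sd`, `n`,
#'   `lambda`, `score`.
#' @export
#' @examples
#' mechanistic_score_from_stats(621.3, 6.0, 5)$score  # 628.008...
mechanistic_score_from_stats <- function(m, sd, n, lambda = 2.5,
                                         peptide = NA_character_) {
  if (!is.finite(n) || n < 1) stop_validation("n must be >= 1")
  if (is.na(sd) || sd < 0) stop_validation("sd must be >= 0")
  if (n <= .Machine$integer.max) n <- as.integer(n)
  structure(list(peptide = peptide, m = m, v = sd^2, sd = sd,
                 n = n, lambda = lambda,
                 score = m + lambda * sd / sqrt(n)),
            class = "mech_score")
}

#' Mechanistic score from replica maximum forces
#'
#' Uses the arithmetic mean and the unbiased (n - 1) sample variance, so
#' it agrees with [mechanistic_score_from_stats()] fed the same mean and
#' standard deviation.
#'
#' @param max_forces numeric vector of replica maximum steering forces
#'   (length >= 2) or a `replica_forces` object from [steered_replicas()].
#' @inheritParams mechanistic_score_from_stats
#' @return A `mech_score`.
#' @export
mechanistic_score_from_replicas <- function(max_forces, lambda = 2.5,
                                            peptide = NA_character_) {
  if (inherits(max_forces, "replica_forces")) {
    peptide <- max_forces$peptide
    max_forces <- max_forces$max_forces
  }
  if (length(max_forces) < 2L) {
    stop_validation("variance-based scoring needs at least 2 replicas")
  }
  if (any(!is.finite(max_forces))) stop_validation("forces must be finite")
  mechanistic_score_from_stats(mean(max_forces), stats::sd(max_forces),
                               length(max_forces), lambda, peptide)
}

#' @export
print.mech_score <- function(x, ...) {
  cat(sprintf("mechanistic score %s: m = %s, sd = %s, n = %s -> %s\n",
              if (is.na(x$peptide)) "" else x$peptide,
              fmt1(x$m), fmt1(x$sd), format(x$n), fmt1(x$score)))
  invisible(x)
}

#' Rank peptides by mechanistic score
#'
#' Ascending score (lower steering force = better permeability); ties are
#' broken by lower mean, then id. Rank 1 comes first.
#'
#' @param scores a list of `mech_score` objects.
#' @return A data frame of class `cpp_ranking` with columns `rank`,
#'   `peptide`, `mean`, `sd`, `n`, `score`.
#' @export
rank_peptides <- function(scores) {
  if (inherits(scores, "mech_score")) scores <- list(scores)
  if (length(scores) == 0L) stop_validation("no scores to rank")
  df <- data.frame(
    peptide = vapply(scores, function(s) s$peptide, ""),
    mean = vapply(scores, function(s) s$m, 0),
    sd = vapply(scores, function(s) s$sd, 0),
    n = vapply(scores, function(s) as.numeric(s$n), 0),
    score = vapply(scores, function(s) s$score, 0),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$score, df$mean, df$peptide), , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  class(df) <- c("cpp_ranking", "data.frame")
  df
}

#' @export
print.cpp_ranking <- function(x, ...) {
  cat("peptides ranked by mechanistic score (lower = better):\n")
  print(format_ranking(x), row.names = FALSE)
  invisible(x)
}

format_ranking <- function(x) {
  data.frame(Rank = x$rank, Peptide = x$peptide, Mean = fmt1(x$mean),
             `Standard deviation` = fmt1(x$sd),
             `Mechanistic score` = fmt1(x$score),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Emit a ranking as a force-table TSV
#'
#' Columns Peptide / Mean / Standard deviation / Mechanistic score with
#' one-decimal formatting (round half away from zero), ascending score.
#'
#' @param scores a list of `mech_score` objects or a `cpp_ranking`.
#' @param path optional output TSV path.
#' @return The formatted data frame, invisibly when written.
#' @export
report_table1 <- function(scores, path = NULL) {
  ranking <- if (inherits(scores, "cpp_ranking")) scores else
    rank_peptides(scores)
  out <- format_ranking(ranking)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Reference table of replica steering-force statistics
#'
#' The bundled ten-peptide table of per-peptide mean and standard deviation
#' of the maximum steering force over five pulling replicas (kJ mol^-1
#' nm^-1), together with the reference mechanistic scores, used as a fixed
#' input for validating the scoring arithmetic and ranking order.
#'
#' @return A data frame with columns `peptide`, `mean`, `sd`,
#'   `printed_score`.
#' @export
reference_force_table <- function() {
  path <- system.file("extdata", "table1_steering_forces.tsv",
                      package = "cppforge")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Score a directory of force-trace files or a statistics table
#'
#' `score_force_files()` groups xvg trace files by peptide (file names
#' `<id>_rep<k>.xvg` or an explicit grouping), extracts each replica's
#' maximum steering force and returns mechanistic scores.
#' `score_force_stats()` scores a data frame of (id, mean, sd, n) rows.
#'
#' @param paths named list: peptide id -> character vector of trace files.
#' @param lambda trade-off parameter (default 2.5).
#' @param smooth_window passed to [max_steering_force()].
#' @return A list of `mech_score` objects.
#' @export
score_force_files <- function(paths, lambda = 2.5, smooth_window = 0L) {
  lapply(names(paths), function(id) {
    maxima <- vapply(paths[[id]], function(p) {
      max_steering_force(read_force_trace(p), smooth_window)
    }, 0)
    mechanistic_score_from_replicas(unname(maxima), lambda, peptide = id)
  })
}

#' @rdname score_force_files
#' @param stats data frame with columns `peptide` (or `id`), `mean`, `sd`
#'   and optionally `n` (default 5).
#' @export
score_force_stats <- function(stats, lambda = 2.5) {
  id_col <- if ("peptide" %in% names(stats)) "peptide" else "id"
  n <- if ("n" %in% names(stats)) stats$n else rep(5L, nrow(stats))
  lapply(seq_len(nrow(stats)), function(i) {
    mechanistic_score_from_stats(stats$mean[i], stats$sd[i], n[i], lambda,
                                 peptide = stats[[id_col]][i])
  })
}
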