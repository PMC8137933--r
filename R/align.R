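# Global alignment machinery for the shuffled-sequence null analysis:
# BLOSUM62 loading, affine-gap Needleman-Wunsch with a deterministic
# traceback, and a center-star progressive multiple alignment.

.cppforge_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Parsed from the standard NCBI text-format matrix shipped with the package
#' (`inst/extdata/BLOSUM62.txt`, entries for the 20 standard amino acids).
#'
#' @return A 20 x 20 integer matrix with residue dimnames.
#' @export
#' @examples
#' blosum62()["W", "W"]  # 11
blosum62 <- function() {
  if (!is.null(.cppforge_env$blosum62)) return(.cppforge_env$blosum62)
  path <- system.file("extdata", "BLOSUM62.txt", package = "cppforge")
  m <- read_ncbi_matrix(path)
  .cppforge_env$blosum62 <- m
  m
}

# Parse an NCBI-format substitution matrix ('#' comments, header row of
# residue letters, one labelled row per residue).
read_ncbi_matrix <- function(path) {
  if (!file.exists(path)) stop_io("no such matrix file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n <- length(header)
  m <- matrix(NA_integer_, n, n, dimnames = list(header, header))
  for (ln in lines[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != n + 1L) {
      stop_io("malformed matrix row in '", path, "': ", ln)
    }
    m[parts[[1]], ] <- as.integer(parts[-1])
  }
  if (anyNA(m)) stop_io("incomplete substitution matrix in '", path, "'")
  m
}

#' Affine-gap global (Needleman-Wunsch) alignment of two peptides
#'
#' Optimal global alignment under an affine gap model in which a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`. The traceback is
#' deterministic: on ties it prefers a substitution over a gap in `b`
#' (deletion) over a gap in `a` (insertion).
#'
#' @param a,b residue strings or length-one [peptides] objects.
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open penalty for the first position of a gap (default -10).
#' @param gap_extend penalty for each further gap position (default -1).
#' @return A list of class `pairwise_alignment` with elements `score`,
#'   `aligned_a`, `aligned_b` (equal-length gapped strings) and `identity`
#'   (identical positions / alignment length).
#' @export
#' @examples
#' needleman_wunsch("W", "W")$score  # 11
needleman_wunsch <- function(a, b, matrix = blosum62(),
                             gap_open = -10, gap_extend = -1) {
  sa <- strsplit(as_residue_string(a), "", fixed = TRUE)[[1]]
  sb <- strsplit(as_residue_string(b), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(c(sa, sb)), rownames(matrix))
  if (length(bad) > 0L) {
    stop_validation("residue '", bad[[1]], "' absent from substitution matrix")
  }
  n <- length(sa); m <- length(sb)
  NEG <- -1e18
  # M: a[i] aligned to b[j]; X: gap in b (consumes a); Y: gap in a (consumes b)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n >= 1L) X[2L:(n + 1L), 1L] <- gap_open + (0:(n - 1L)) * gap_extend
  if (m >= 1L) Y[1L, 2L:(m + 1L)] <- gap_open + (0:(m - 1L)) * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- matrix[sa[i], sb[j]]
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open, X[i, j + 1L] + gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open, Y[i + 1L, j] + gap_extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback, tie preference: M (match) > X (delete) > Y (insert)
  i <- n; j <- m
  state <- if (M[n + 1L, m + 1L] >= score) "M" else
    if (X[n + 1L, m + 1L] >= score) "X" else "Y"
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      ra <- c(sa[i], ra); rb <- c(sb[j], rb)
      s <- matrix[sa[i], sb[j]]
      target <- M[i + 1L, j + 1L] - s
      state <- if (M[i, j] >= target) "M" else if (X[i, j] >= target) "X" else "Y"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      ra <- c(sa[i], ra); rb <- c("-", rb)
      cur <- X[i + 1L, j + 1L]
      state <- if (i - 1L >= 0L && M[i, j + 1L] + gap_open >= cur) "M" else "X"
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(sb[j], rb)
      cur <- Y[i + 1L, j + 1L]
      state <- if (j - 1L >= 0L && M[i + 1L, j] + gap_open >= cur) "M" else "Y"
      j <- j - 1L
    }
    if (i == 0L && j > 0L && state != "Y") state <- "Y"
    if (j == 0L && i > 0L && state != "X") state <- "X"
  }
  aligned_a <- paste(ra, collapse = "")
  aligned_b <- paste(rb, collapse = "")
  len <- nchar(aligned_a)
  ident <- if (len == 0L) 1 else sum(ra == rb & ra != "-") / len
  structure(list(score = score, aligned_a = aligned_a, aligned_b = aligned_b,
                 identity = ident),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("global alignment, score", x$score,
      sprintf("(identity %.2f)\n", x$identity))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Center-star progressive multiple sequence alignment
#'
#' The center sequence maximizes the summed pairwise [needleman_wunsch()]
#' scores against all others (ties broken by input order); the remaining
#' sequences are merged against it under the "once a gap, always a gap"
#' rule. Rows all have equal length and degapping any row recovers the
#' input sequence.
#'
#' @param x a [peptides] object with at least two sequences.
#' @inheritParams needleman_wunsch
#' @return An object of class `peptide_msa`: a character matrix of single
#'   letters (rows = sequences, named), with the center id as attribute.
#' @export
star_msa <- function(x, matrix = blosum62(), gap_open = -10, gap_extend = -1) {
  if (length(x) < 2L) stop_validation("star_msa needs at least 2 sequences")
  n <- length(x)
  scores <- base::matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- needleman_wunsch(x[i], x[j], matrix, gap_open, gap_extend)$score
      scores[i, j] <- s; scores[j, i] <- s
    }
  }
  center <- which.max(rowSums(scores))
  master <- strsplit(unclass(x)[[center]], "", fixed = TRUE)[[1]]
  rows <- list()
  rows[[center]] <- master
  others <- setdiff(seq_len(n), center)
  for (k in others) {
    aln <- needleman_wunsch(paste(master[master != "-"], collapse = ""),
                            x[k], matrix, gap_open, gap_extend)
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    # map the freshly aligned center (ca) onto the gapped master, inserting
    # any new gap columns into all previously merged rows
    merged_new <- character(0)  # new row, in master coordinates
    mi <- 1L  # index into master
    insertions <- integer(0)  # master positions before which to insert columns
    for (t in seq_along(ca)) {
      if (ca[t] == "-") {
        if (mi <= length(master) && master[mi] == "-") {
          # reuse an existing gap column of the master
          merged_new <- c(merged_new, cb[t])
          mi <- mi + 1L
        } else {
          # new column relative to master
          insertions <- c(insertions, mi)
          merged_new <- c(merged_new, cb[t])
        }
      } else {
        while (mi <= length(master) && master[mi] == "-") {
          merged_new <- c(merged_new, "-")
          mi <- mi + 1L
        }
        merged_new <- c(merged_new, cb[t])
        mi <- mi + 1L
      }
    }
    while (mi <= length(master)) {
      merged_new <- c(merged_new, "-"); mi <- mi + 1L
    }
    if (length(insertions) > 0L) {
      master <- insert_gaps(master, insertions)
      for (r in seq_along(rows)) {
        if (!is.null(rows[[r]]) && r != k) rows[[r]] <- insert_gaps(rows[[r]], insertions)
      }
      rows[[center]] <- master
    }
    rows[[k]] <- merged_new
  }
  width <- length(master)
  msa <- base::matrix("-", n, width, dimnames = list(names(x), NULL))
  for (r in seq_len(n)) msa[r, ] <- rows[[r]]
  structure(msa, class = "peptide_msa", center = names(x)[center])
}

# Insert gap columns before the given (1-based, pre-insertion) positions.
insert_gaps <- function(row, positions) {
  out <- character(length(row) + length(positions))
  tab <- tabulate(positions, nbins = length(row) + 1L)
  oi <- 1L
  for (p in seq_along(row)) {
    if (tab[p] > 0L) {
      out[oi:(oi + tab[p] - 1L)] <- "-"
      oi <- oi + tab[p]
    }
    out[oi] <- row[p]
    oi <- oi + 1L
  }
  if (tab[length(row) + 1L] > 0L) {
    out[oi:(oi + tab[length(row) + 1L] - 1L)] <- "-"
  }
  out
}

#' @export
print.peptide_msa <- function(x, ...) {
  cat("multiple alignment:", nrow(x), "sequences x", ncol(x),
      "columns (center:", attr(x, "center"), ")\n")
  ids <- rownames(x)
  for (r in seq_len(min(nrow(x), 12L))) {
    cat(sprintf("  %-20s %s\n", ids[r], paste(x[r, ], collapse = "")))
  }
  if (nrow(x) > 12L) cat("  ...\n")
  invisible(x)
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa a `peptide_msa` from [star_msa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(msa))) {
    writeLines(paste0(">", rownames(msa)[r]), con)
    writeLines(paste(msa[r, ], collapse = ""), con)
  }
  invisible(path)
}

as_residue_string <- function(x) {
  if (inherits(x, "peptide_set")) {
    if (length(x) != 1L) stop_validation("expected a single sequence")
    return(unclass(x)[[1]])
  }
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop_validation("expected a residue string")
}
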