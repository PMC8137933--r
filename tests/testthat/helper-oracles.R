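# Shared helpers: independent alignment oracle, sum-of-pairs scorer and
# small random fixtures.

# Independent brute-force global-alignment optimum: top-down enumeration
# over the three column types with the affine convention
# gap(len) = open + (len - 1) * extend. Memoized on (i, j, previous column
# type); structurally different from the package's bottom-up three-matrix
# dynamic programme.
nw_oracle <- function(a, b, mat = blosum62(), open = -10, ext = -1) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(sa)
  lb <- length(sb)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i == la && j == lb) return(0)
    key <- paste0(i, ",", j, ",", prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i < la && j < lb) {
      best <- max(best, mat[sa[i + 1], sb[j + 1]] + rec(i + 1, j + 1, "M"))
    }
    if (i < la) {
      best <- max(best, (if (prev == "X") ext else open) + rec(i + 1, j, "X"))
    }
    if (j < lb) {
      best <- max(best, (if (prev == "Y") ext else open) + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(0L, 0L, "M")
}

# Affine sum-of-pairs score of an alignment matrix (rows = sequences).
sp_score <- function(rows, mat = blosum62(), open = -10, ext = -1) {
  n <- nrow(rows)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r1 <- rows[i, ]
      r2 <- rows[j, ]
      keep <- !(r1 == "-" & r2 == "-")
      r1 <- r1[keep]
      r2 <- r2[keep]
      state <- "M"
      for (t in seq_along(r1)) {
        if (r1[t] != "-" && r2[t] != "-") {
          total <- total + mat[r1[t], r2[t]]
          state <- "M"
        } else if (r1[t] == "-") {
          total <- total + if (state == "Y") ext else open
          state <- "Y"
        } else {
          total <- total + if (state == "X") ext else open
          state <- "X"
        }
      }
    }
  }
  total
}

# All residue strings over `alphabet` with lengths 0..max_len.
all_strings_upto <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (l in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

rand_peptides <- function(n, len_range = c(6L, 12L), seed = 1L,
                          alphabet = cppforge:::AA_STANDARD) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    peptides(vapply(seq_len(n), function(i) {
      paste(sample(alphabet, sample(len_range[1]:len_range[2], 1L),
                   replace = TRUE), collapse = "")
    }, ""))
  })
}

degap <- function(row) paste(row[row != "-"], collapse = "")
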