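#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed from a master seed plus arbitrary string/integer
# labels (stage names, peptide ids, replica indices). Kept below 2^31 - 1.
derive_seed <- function(master, ...) {
  p <- 2147483629
  h <- as.double(master) %% p
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(":", as.character(part)))) {
      h <- (h * 131 + ch) %% p
    }
  }
  as.integer(h)
}

# Round half away from zero at `digits` decimals (matches the one-decimal
# reporting convention used throughout force tables).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt1 <- function(x) sprintf("%.1f", round_half_away(x, 1))

stop_validation <- function(...) {
  stop(structure(
    class = c("cppforge_validation_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

stop_io <- function(...) {
  stop(structure(
    class = c("cppforge_io_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
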