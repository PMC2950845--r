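# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched. seed = NULL runs expr as-is.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Split one protein sequence string into a character vector of residues.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

assert_protein <- function(seq, what = "sequence", allow_x = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  ok <- AA_STANDARD
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(seq_chars(seq)), ok)
  if (length(bad))
    stop(what, " contains non-standard residues: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(seq)
}

# 0-based half-open interval overlap test
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
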