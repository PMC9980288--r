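# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over the DNA alphabet (N maps to N).
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("TCA", "ACGT"))
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  out <- vapply(strsplit(comp, "", fixed = TRUE),
                function(s) paste(rev(s), collapse = ""), "")
  out[is.na(x)] <- NA_character_
  out
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Longest common prefix length of two equal-length character vectors.
lcp_length <- function(a, b) {
  mapply(function(x, y) {
    n <- min(nchar(x), nchar(y))
    if (n == 0L) return(0L)
    xs <- substring(x, seq_len(n), seq_len(n))
    ys <- substring(y, seq_len(n), seq_len(n))
    neq <- which(xs != ys)
    if (length(neq)) neq[1L] - 1L else n
  }, a, b, USE.NAMES = FALSE)
}

# Count occurrences of a (possibly lookahead) regex in each string.
count_pattern <- function(x, pattern, fixed = FALSE) {
  m <- gregexpr(pattern, x, perl = !fixed, fixed = fixed)
  vapply(m, function(g) if (g[1L] == -1L) 0L else length(g), 0L)
}

# Weighted sampling without replacement by rejection; multinomial marginals
# are preserved to excellent approximation when n << length(ids).
sample_unique <- function(ids, n, weights = NULL, exclude = NULL,
                          what = "sites") {
  if (n == 0L) return(integer(0))
  if (is.null(weights)) {
    pool <- if (length(exclude)) setdiff(ids, exclude) else ids
    if (length(pool) < n)
      stop(sprintf("cannot draw %d distinct %s from %d available", n, what,
                   length(pool)), call. = FALSE)
    return(sample(pool, n))
  }
  w <- weights
  if (length(exclude)) w[match(exclude, ids)] <- 0
  if (sum(w > 0) < n)
    stop(sprintf("cannot draw %d distinct %s from %d available", n, what,
                 sum(w > 0)), call. = FALSE)
  chosen <- integer(0)
  for (i in 1:50) {
    draw <- sample(ids, min(n * 2L, length(ids)), replace = TRUE, prob = w)
    chosen <- unique(c(chosen, draw))
    if (length(chosen) >= n) return(chosen[seq_len(n)])
  }
  stop(sprintf("failed to draw %d distinct %s after bounded retries", n, what),
       call. = FALSE)
}
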