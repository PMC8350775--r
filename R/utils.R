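# Internal sequence helpers. Sequences are plain uppercase character scalars
# over {A,C,G,T,N}; all internal coordinates are 0-based half-open.

#' @importFrom Biostrings DNAString reverseComplement
.revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.complement_chr <- function(x) chartr("ACGTN", "TGCAN", x)

# substring window vector: all k-mers of s (1-based starts)
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

.seq_bytes <- function(s) as.integer(charToRaw(s))

# substring by 0-based half-open interval
.sub0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

# extract interval that may wrap the origin of a circular sequence
.sub0_circ <- function(s, start, end, wraps) {
  L <- nchar(s)
  if (!wraps) return(.sub0(s, start, end))
  paste0(.sub0(s, start, L), .sub0(s, 0L, end))
}

.interval_len <- function(start, end, wraps, L) {
  ifelse(wraps, L - start + end, end - start)
}

# validate a DNA string; returns NULL or the 1-based offset of the first bad char
.first_bad_residue <- function(s) {
  m <- regexpr("[^ACGTN]", s)
  if (m[1] == -1L) NULL else as.integer(m[1])
}

# deterministic local RNG scope
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
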