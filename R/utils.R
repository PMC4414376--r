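## Small sequence helpers shared across modules. Sequences are plain uppercase
## character scalars over {A,C,G,T,N}; byte-level work goes through charToRaw.

#' Reverse complement of a nucleotide string
#'
#' Complements A/C/G/T (N maps to N) and reverses. Input must already be
#' normalized (uppercase, alphabet {A,C,G,T,N}).
#'
#' @param seq character scalar.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  r <- rev(charToRaw(seq))
  out <- .COMPLEMENT[as.integer(r) + 1L]
  if (anyNA(out)) stop("revcomp: sequence contains characters outside {A,C,G,T,N}")
  rawToChar(as.raw(out))
}

.COMPLEMENT <- local({
  m <- rep(NA_integer_, 256L)
  from <- utf8ToInt("ACGTN")
  to <- utf8ToInt("TGCAN")
  m[from + 1L] <- to
  m
})

## vectorized revcomp
revcomp_all <- function(x) vapply(x, revcomp, "", USE.NAMES = FALSE)

## all rotations of a string
rotations <- function(s) {
  k <- nchar(s)
  if (k == 1L) return(s)
  d <- paste0(s, s)
  vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), "")
}

## TRUE if s is a repetition of a proper sub-motif (minimal period < nchar)
is_reducible_motif <- function(s) {
  k <- nchar(s)
  if (k == 1L) return(FALSE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (strrep(substr(s, 1L, d), k %/% d) == s) return(TRUE)
  }
  FALSE
}

## stop() with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
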