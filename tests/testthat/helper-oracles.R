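# Independent oracles used to validate the package's core computations.

# Exhaustive SSR scan: for every (start, motif length) pair, count how many
# full units repeat from that start; report maximal-run starts only. Written
# position-by-position, independently of the package's run-length scan.
find_ssrs_oracle <- function(seq, params = ssr_params()) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  out <- list()
  for (k in params$motif_lengths) {
    minu <- params$min_units[k]
    i <- 1L
    while (i + k * minu - 1L <= n) {
      motif <- ch[i:(i + k - 1L)]
      if (any(motif == "N")) { i <- i + 1L; next }
      u <- 1L
      while (i + (u + 1L) * k - 1L <= n &&
             identical(motif, ch[(i + u * k):(i + (u + 1L) * k - 1L)]))
        u <- u + 1L
      if (u >= minu) {
        # maximal start: the equality run must not extend to the left
        left_ext <- i > 1L && ch[i - 1L] != "N" && ch[i - 1L] == ch[i - 1L + k]
        motif_str <- paste(motif, collapse = "")
        if (!left_ext && !microsynt:::is_reducible_motif(motif_str)) {
          out[[length(out) + 1L]] <- data.frame(
            start = i - 1L, end = i - 1L + u * k,
            motif = canonical_motif(motif_str),
            motif_len = k, n_units = u, stringsAsFactors = FALSE)
        }
        i <- i + u * k - k + 1L   # next possible distinct run start
      } else {
        i <- i + 1L
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(start = integer(), end = integer(), motif = character(),
                      motif_len = integer(), n_units = integer())
  res <- res[order(res$start, res$motif_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Two-sided Fisher P by explicit hypergeometric enumeration: sum the point
# probabilities of all tables (with the observed margins) no more likely than
# the observed one. The relative slack mirrors the conventional guard against
# ties broken by floating-point noise.
fisher_oracle <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  x <- max(0L, col1 - row2):min(col1, row1)
  probs <- dhyper(x, row1, row2, col1)
  pobs <- dhyper(a, row1, row2, col1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

random_seq <- function(n, with_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (with_n > 0) {
    k <- rbinom(1L, n, with_n)
    if (k > 0) s[sample.int(n, k)] <- "N"
  }
  paste(s, collapse = "")
}

# small assembly from literal sequences
asm <- function(...) assembly(c(...))
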