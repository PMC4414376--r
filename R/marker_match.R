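## One-to-one homologous SSR locus matching between two assemblies.
## Homology is decided on flank similarity (the repeat itself carries no
## positional information): semi-global alignment of the left and right
## flanks, in both the given and the reverse-complement orientation, followed
## by a reciprocal-best-hit filter with a tie margin. Left and right flanks
## are aligned separately, which also prevents the aligner from bridging
## across the repeat.

#' Marker matching parameters
#'
#' @param min_identity minimum alignment identity for an accepted pair.
#' @param min_aligned_fraction minimum aligned columns relative to the shorter
#'   combined flank.
#' @param require_same_motif restrict candidates to loci with the same
#'   canonical motif.
#' @param tie_margin a locus is dropped as ambiguous when its best and
#'   second-best candidate identities differ by less than this.
#' @param match,mismatch,gap_open,gap_extend alignment scoring.
#' @param kmer_len,min_shared_kmers candidate prefilter: pairs must share at
#'   least `min_shared_kmers` distinct strand-canonical k-mers between their
#'   flanks before alignment is attempted.
#' @return list of class `match_params`.
#' @export
match_params <- function(min_identity = 0.90,
                         min_aligned_fraction = 0.80,
                         require_same_motif = TRUE,
                         tie_margin = 0.02,
                         match = 1, mismatch = -1,
                         gap_open = 2, gap_extend = 1,
                         kmer_len = 12L, min_shared_kmers = 5L) {
  stopifnot(min_identity > 0, min_identity <= 1)
  structure(list(min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction,
                 require_same_motif = require_same_motif,
                 tie_margin = tie_margin,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 kmer_len = as.integer(kmer_len),
                 min_shared_kmers = as.integer(min_shared_kmers)),
            class = "match_params")
}

.subst_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch)
}

## Align two equal-length character vectors elementwise (overlap alignment,
## free end gaps). Empty strings contribute zero matches and zero columns.
align_batch <- function(a, b, params) {
  n <- length(a)
  nm <- numeric(n); nc <- numeric(n)
  ok <- nzchar(a) & nzchar(b)
  if (any(ok)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(a[ok]), Biostrings::DNAStringSet(b[ok]),
      type = "overlap",
      substitutionMatrix = .subst_matrix(params),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    nm[ok] <- Biostrings::nmatch(al)
    nc[ok] <- Biostrings::nchar(al)
  }
  list(nmatch = nm, ncol = nc)
}

## identity/orientation for flank quadruples, vectorized over pairs
flank_identity_batch <- function(la, ra, lb, rb, params) {
  plus1 <- align_batch(la, lb, params)
  plus2 <- align_batch(ra, rb, params)
  minus1 <- align_batch(la, revcomp_all(rb), params)
  minus2 <- align_batch(ra, revcomp_all(lb), params)
  id_plus <- (plus1$nmatch + plus2$nmatch) / pmax(plus1$ncol + plus2$ncol, 1)
  id_minus <- (minus1$nmatch + minus2$nmatch) / pmax(minus1$ncol + minus2$ncol, 1)
  tot_a <- nchar(la) + nchar(ra)
  tot_b <- nchar(lb) + nchar(rb)
  shorter <- pmax(pmin(tot_a, tot_b), 1)
  af_plus <- pmin((plus1$ncol + plus2$ncol) / shorter, 1)
  af_minus <- pmin((minus1$ncol + minus2$ncol) / shorter, 1)
  ## orientation is decided on total matches, not identity: a short spurious
  ## perfect overlap in the wrong orientation must not beat a long
  ## near-perfect alignment in the right one
  use_minus <- (minus1$nmatch + minus2$nmatch) > (plus1$nmatch + plus2$nmatch)
  data.frame(identity = ifelse(use_minus, id_minus, id_plus),
             orientation = ifelse(use_minus, "-", "+"),
             aligned_fraction = ifelse(use_minus, af_minus, af_plus),
             stringsAsFactors = FALSE)
}

#' Flank similarity between two SSR loci
#'
#' Semi-global (free end gap) alignment of left-vs-left and right-vs-right
#' flanks in the given orientation, and of left-vs-reverse-complemented-right
#' in the flipped orientation; the better orientation is returned. Identity is
#' matches over aligned columns, pooled over the two flank alignments.
#'
#' @param left_a,right_a flanks of the first locus.
#' @param left_b,right_b flanks of the second locus.
#' @param params [match_params()].
#' @return list with `identity`, `orientation` ("+"/"-"), `aligned_fraction`.
#' @export
flank_identity <- function(left_a, right_a, left_b, right_b,
                           params = match_params()) {
  if (!nzchar(left_a) && !nzchar(right_a))
    abort("flank_identity: first locus has empty flanks")
  if (!nzchar(left_b) && !nzchar(right_b))
    abort("flank_identity: second locus has empty flanks")
  res <- flank_identity_batch(left_a, right_a, left_b, right_b, params)
  list(identity = res$identity, orientation = res$orientation,
       aligned_fraction = res$aligned_fraction)
}

## distinct strand-canonical k-mers of a locus' combined flanks
flank_kmer_table <- function(left, right, k) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }
  res <- lapply(seq_along(left), function(i) {
    km <- c(kmers_of(left[i]), kmers_of(right[i]))
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (!length(km)) return(NULL)
    km <- unique(pmin(km, revcomp_all(km)))
    data.frame(kmer = km, idx = i, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(kmer = character(), idx = integer()) else out
}

#' Match SSR loci one-to-one between two assemblies
#'
#' Candidate pairs are restricted to loci with the same canonical motif (when
#' `require_same_motif`) sharing at least `min_shared_kmers` flank k-mers. A
#' pair is accepted only if its identity and aligned fraction pass the
#' thresholds AND it is the reciprocal best hit for both loci with the
#' second-best identity lower by at least `tie_margin`; loci with a tie within
#' the margin are dropped entirely.
#'
#' @param loci_a,loci_b data.frames from [extract_flanks()].
#' @param params [match_params()].
#' @return data.frame of marker pairs: per-side scaffold/start/end/locus id,
#'   `motif`, `identity`, `aligned_fraction`, `orientation`.
#' @export
match_markers <- function(loci_a, loci_b, params = match_params()) {
  a <- loci_a[loci_a$usable, , drop = FALSE]
  b <- loci_b[loci_b$usable, , drop = FALSE]
  empty <- data.frame(locus_a = character(), scaffold_a = character(),
                      start_a = integer(), end_a = integer(),
                      locus_b = character(), scaffold_b = character(),
                      start_b = integer(), end_b = integer(),
                      motif = character(), identity = numeric(),
                      aligned_fraction = numeric(), orientation = character(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)

  ka <- flank_kmer_table(a$left_flank, a$right_flank, params$kmer_len)
  kb <- flank_kmer_table(b$left_flank, b$right_flank, params$kmer_len)
  mm <- merge(ka, kb, by = "kmer", suffixes = c("_a", "_b"))
  if (nrow(mm) == 0L) return(empty)
  key <- paste(mm$idx_a, mm$idx_b)
  shared <- table(key)
  cand <- do.call(rbind, strsplit(names(shared), " ", fixed = TRUE))
  cand <- data.frame(i = as.integer(cand[, 1L]), j = as.integer(cand[, 2L]),
                     shared = as.integer(shared))
  cand <- cand[cand$shared >= params$min_shared_kmers, , drop = FALSE]
  if (params$require_same_motif)
    cand <- cand[a$motif[cand$i] == b$motif[cand$j], , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  sc <- flank_identity_batch(a$left_flank[cand$i], a$right_flank[cand$i],
                             b$left_flank[cand$j], b$right_flank[cand$j],
                             params)
  cand <- cbind(cand, sc)

  ## reciprocal best hit with tie margin; ties drop the locus outright
  best_with_margin <- function(idx_col) {
    grp <- split(seq_len(nrow(cand)), cand[[idx_col]])
    res <- lapply(grp, function(rows) {
      ids <- cand$identity[rows]
      o <- order(ids, decreasing = TRUE)
      second <- if (length(o) > 1L) ids[o[2L]] else 0
      list(row = rows[o[1L]], clear = ids[o[1L]] - second >= params$tie_margin)
    })
    list(row = vapply(res, `[[`, 0L, "row"),
         clear = vapply(res, `[[`, NA, "clear"),
         who = as.integer(names(grp)))
  }
  ba <- best_with_margin("i")
  bb <- best_with_margin("j")
  best_a <- setNames(ba$row, ba$who)   # locus i -> best candidate row
  best_b <- setNames(bb$row, bb$who)
  clear_a <- setNames(ba$clear, ba$who)
  clear_b <- setNames(bb$clear, bb$who)

  rows <- unname(best_a)
  keep <- logical(length(rows))
  for (r in seq_along(rows)) {
    row <- rows[r]
    i <- cand$i[row]; j <- cand$j[row]
    keep[r] <- isTRUE(clear_a[[as.character(i)]]) &&
      isTRUE(clear_b[[as.character(j)]]) &&
      best_b[[as.character(j)]] == row &&
      cand$identity[row] >= params$min_identity &&
      cand$aligned_fraction[row] >= params$min_aligned_fraction
  }
  rows <- rows[keep]
  out <- data.frame(
    locus_a = a$locus_id[cand$i[rows]],
    scaffold_a = a$scaffold[cand$i[rows]],
    start_a = a$start[cand$i[rows]],
    end_a = a$end[cand$i[rows]],
    locus_b = b$locus_id[cand$j[rows]],
    scaffold_b = b$scaffold[cand$j[rows]],
    start_b = b$start[cand$j[rows]],
    end_b = b$end[cand$j[rows]],
    motif = a$motif[cand$i[rows]],
    identity = cand$identity[rows],
    aligned_fraction = cand$aligned_fraction[rows],
    orientation = cand$orientation[rows],
    stringsAsFactors = FALSE)
  out[order(out$scaffold_a, out$start_a), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
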