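## Microsatellite (SSR) detection. Perfect tandem repeats of motif length 1-6
## are the synteny markers; the repeat itself is uninformative for homology,
## so each locus also carries up to flank_len bases of flanking sequence on
## either side (truncated at scaffold ends and at N bases).

#' SSR detection parameters
#'
#' MISA-style defaults: minimum 12 units for mononucleotide repeats, 6 for
#' dinucleotide, 5 for tri- through hexanucleotide. Only perfect repeats are
#' detected.
#'
#' @param min_units integer vector of length 6: minimum repeat units for motif
#'   lengths 1..6.
#' @param motif_lengths motif lengths to scan (subset of 1..6).
#' @param flank_len bases of flanking sequence extracted on each side.
#' @param min_flank_total loci whose combined flanks are shorter than this are
#'   marked unusable for matching.
#' @return list of class `ssr_params`.
#' @export
ssr_params <- function(min_units = c(12L, 6L, 5L, 5L, 5L, 5L),
                       motif_lengths = 1:6,
                       flank_len = 200L,
                       min_flank_total = 60L) {
  stopifnot(length(min_units) == 6L, all(motif_lengths %in% 1:6))
  if (any(min_units[2:6] < 2L))
    abort("ssr_params: minimum units must be >= 2 for motif length >= 2")
  structure(list(min_units = as.integer(min_units),
                 motif_lengths = as.integer(motif_lengths),
                 flank_len = as.integer(flank_len),
                 min_flank_total = as.integer(min_flank_total)),
            class = "ssr_params")
}

#' Canonical representative of an SSR motif
#'
#' The lexicographically smallest string among all rotations of the motif and
#' all rotations of its reverse complement, so that the same repeat found on
#' either strand or in any phase maps to one name.
#'
#' @param motif string over \{A,C,G,T\}, length 1-6, not itself a repetition
#'   of a shorter motif.
#' @return canonical motif string.
#' @export
canonical_motif <- function(motif) {
  k <- nchar(motif)
  if (k < 1L || k > 6L) abort("canonical_motif: motif length must be 1-6")
  if (grepl("[^ACGT]", motif)) abort("canonical_motif: motif must be over {A,C,G,T}")
  if (is_reducible_motif(motif))
    abort("canonical_motif: motif '%s' is a repetition of a shorter motif", motif)
  min(c(rotations(motif), rotations(revcomp(motif))))
}

#' Find perfect SSR loci in one sequence
#'
#' All maximal perfect tandem runs whose unit count meets the per-motif-length
#' minimum. Runs never cross an N. A run whose motif is reducible (for
#' example "ACAC" as a tetranucleotide) is reported only under its minimal
#' period. Runs are truncated to whole units; loci are sorted by start.
#'
#' @param seq normalized sequence string.
#' @param params [ssr_params()].
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `motif` (canonical), `motif_len`, `n_units`.
#' @export
find_ssrs <- function(seq, params = ssr_params()) {
  r <- charToRaw(seq)
  out <- vector("list", length(params$motif_lengths))
  for (idx in seq_along(params$motif_lengths)) {
    k <- params$motif_lengths[idx]
    min_units <- params$min_units[k]
    min_run <- min_units * k - k          # equality-run length for min units
    runs <- eq_runs(r, k, min_run)
    if (nrow(runs) == 0L) next
    start0 <- runs[, "start"] - 1L        # 0-based tandem-region start
    total <- runs[, "len"] + k            # full run span
    units <- total %/% k
    keep <- units >= min_units
    if (!any(keep)) next
    start0 <- start0[keep]; units <- units[keep]
    motifs <- substring(seq, start0 + 1L, start0 + k)
    irred <- !vapply(motifs, is_reducible_motif, logical(1L), USE.NAMES = FALSE)
    if (!any(irred)) next
    start0 <- start0[irred]; units <- units[irred]; motifs <- motifs[irred]
    out[[idx]] <- data.frame(
      start = start0,
      end = start0 + units * k,
      motif = vapply(motifs, canonical_motif, "", USE.NAMES = FALSE),
      motif_len = k,
      n_units = units,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(start = integer(), end = integer(), motif = character(),
                      motif_len = integer(), n_units = integer())
  res <- res[order(res$start, res$motif_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find SSR loci across a whole assembly
#'
#' @param x Assembly.
#' @param params [ssr_params()].
#' @return data.frame as [find_ssrs()] plus columns `scaffold` and `locus_id`.
#' @export
find_assembly_ssrs <- function(x, params = ssr_params()) {
  stopifnot(inherits(x, "Assembly"))
  res <- lapply(names(x$seq), function(id) {
    df <- find_ssrs(x$seq[[id]], params)
    if (nrow(df) == 0L) return(NULL)
    cbind(data.frame(scaffold = id, stringsAsFactors = FALSE), df)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_len = integer(), n_units = integer())
  out$locus_id <- if (nrow(out)) paste0(out$scaffold, ":", out$start) else character()
  rownames(out) <- NULL
  out
}

#' Extract flanking sequences for SSR loci
#'
#' The left flank is up to `flank_len` bases immediately 5' of the repeat,
#' truncated at the scaffold start and at the nearest N; the right flank is
#' symmetric. Loci whose combined flank length is below `min_flank_total` are
#' marked unusable.
#'
#' @param ssrs data.frame from [find_assembly_ssrs()].
#' @param x the Assembly the loci were detected in.
#' @param params [ssr_params()] (supplies `flank_len` and `min_flank_total`).
#' @return `ssrs` with added columns `left_flank`, `right_flank`, `usable`.
#' @export
extract_flanks <- function(ssrs, x, params = ssr_params()) {
  stopifnot(inherits(x, "Assembly"))
  fl <- params$flank_len
  n <- nrow(ssrs)
  left <- character(n); right <- character(n)
  for (scaf in unique(ssrs$scaffold)) {
    s <- x$seq[[scaf]]
    if (is.null(s)) abort("extract_flanks: scaffold '%s' not in assembly", scaf)
    len <- nchar(s)
    sel <- which(ssrs$scaffold == scaf)
    for (i in sel) {
      st <- ssrs$start[i]; en <- ssrs$end[i]
      if (st < 0L || en > len) abort("extract_flanks: locus outside scaffold '%s'", scaf)
      lf <- substr(s, max(1L, st - fl + 1L), st)
      rf <- substr(s, en + 1L, min(len, en + fl))
      # truncate at nearest N: keep the suffix (left) / prefix (right) up to N
      nl <- gregexpr("N", lf, fixed = TRUE)[[1L]]
      if (nl[1L] != -1L) lf <- substr(lf, max(nl) + 1L, nchar(lf))
      nr <- gregexpr("N", rf, fixed = TRUE)[[1L]]
      if (nr[1L] != -1L) rf <- substr(rf, 1L, min(nr) - 1L)
      left[i] <- lf; right[i] <- rf
    }
  }
  ssrs$left_flank <- left
  ssrs$right_flank <- right
  ssrs$usable <- nchar(left) + nchar(right) >= params$min_flank_total
  ssrs
}

#' Write SSR loci as BED (0-based half-open)
#' @param ssrs data.frame from [find_assembly_ssrs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(ssrs, path) {
  bed <- data.frame(ssrs$scaffold, ssrs$start, ssrs$end,
                    paste0(ssrs$motif, "x", ssrs$n_units))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
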