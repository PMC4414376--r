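## Assembly summary statistics: N50 and friends, computed on scaffold spans
## (including N) and on N-free contig lengths.

#' N-statistic of a set of segment lengths
#'
#' The smallest length L such that segments of length >= L jointly cover at
#' least `fraction` of the total (N50 for `fraction = 0.5`).
#'
#' @param lengths positive integer vector.
#' @param fraction real in (0, 1], default 0.5.
#' @return integer length.
#' @export
nstat <- function(lengths, fraction = 0.5) {
  if (length(lengths) == 0L) abort("nstat: empty length vector")
  stopifnot(all(lengths > 0), fraction > 0, fraction <= 1)
  srt <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(srt)
  srt[which(cs >= fraction * cs[length(cs)])[1L]]
}

#' Summarize an assembly (Table-2-style statistics)
#'
#' Scaffolds are first filtered to length strictly greater than
#' `min_scaffold_len`; all six statistics are then computed on the filtered
#' set. Scaffold lengths are spans including N; contig lengths are N-free
#' segments from [split_contigs()] (a contig may retain N runs shorter than
#' `min_gap`; those bases count toward contig length but not toward total
#' sequence length).
#'
#' @param x Assembly.
#' @param min_scaffold_len keep scaffolds with span > this value (default 0).
#' @param min_gap N-run length that splits contigs (default 10).
#' @return object of class `AssemblyStats`: list with `assembly`,
#'   `total_sequence_length` (non-N bases), `total_assembly_length` (span
#'   including N), `n_scaffolds`, `scaffold_n50`, `n_contigs`, `contig_n50`.
#' @export
summarize_assembly <- function(x, min_scaffold_len = 0L, min_gap = 10L) {
  stopifnot(inherits(x, "Assembly"))
  spans <- nchar(x$seq)
  keep <- spans > min_scaffold_len
  if (!any(keep))
    abort("summarize_assembly: no scaffolds longer than %d bp", min_scaffold_len)
  sub <- assembly(x$seq[keep], name = x$name)
  spans <- nchar(sub$seq)
  n_count <- vapply(sub$seq, function(s) {
    sum(charToRaw(s) == as.raw(78L))  # 'N'
  }, integer(1L), USE.NAMES = FALSE)
  contigs <- split_contigs(sub, min_gap = min_gap)
  structure(list(
    assembly = x$name,
    total_sequence_length = sum(as.numeric(spans)) - sum(as.numeric(n_count)),
    total_assembly_length = sum(as.numeric(spans)),
    n_scaffolds = sum(keep),
    scaffold_n50 = nstat(spans),
    n_contigs = nrow(contigs),
    contig_n50 = if (nrow(contigs)) nstat(contigs$length) else NA_integer_
  ), class = "AssemblyStats")
}

#' @export
print.AssemblyStats <- function(x, ...) {
  fmt_mb <- function(b) sprintf("%.1f Mb", round(b / 1e6, 1))
  fmt_kb <- function(b) {
    if (is.na(b)) return("NA")
    if (b >= 1e6) fmt_mb(b) else sprintf("%.1f Kb", round(b / 1e3, 1))
  }
  cat(sprintf("Assembly statistics: %s\n", x$assembly))
  cat(sprintf("  Total sequence length  %s\n", fmt_mb(x$total_sequence_length)))
  cat(sprintf("  Total assembly length  %s\n", fmt_mb(x$total_assembly_length)))
  cat(sprintf("  Number of scaffolds    %s\n", format(x$n_scaffolds, big.mark = ",")))
  cat(sprintf("  Scaffold N50           %s\n", fmt_kb(x$scaffold_n50)))
  cat(sprintf("  Number of contigs      %s\n", format(x$n_contigs, big.mark = ",")))
  cat(sprintf("  Contig N50             %s\n", fmt_kb(x$contig_n50)))
  invisible(x)
}

#' @export
as.data.frame.AssemblyStats <- function(x, ...) {
  data.frame(assembly = x$assembly,
             total_sequence_length = x$total_sequence_length,
             total_assembly_length = x$total_assembly_length,
             n_scaffolds = x$n_scaffolds,
             scaffold_n50 = x$scaffold_n50,
             n_contigs = x$n_contigs,
             contig_n50 = x$contig_n50,
             stringsAsFactors = FALSE)
}
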