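## Assembly container and file IO. Coordinates are 0-based half-open
## everywhere inside the package; 1-based inclusive only at the GFF3/BED
## boundary, following each format's convention.

#' Construct an Assembly object
#'
#' An Assembly is a named, ordered collection of scaffold sequences over the
#' alphabet \{A,C,G,T,N\}. Sequences are normalized on construction: lowercase
#' is uppercased and IUPAC ambiguity codes other than N are mapped to N (they
#' cannot anchor SSR or flank matching). Any other character is an error.
#'
#' @param seqs named character vector of scaffold sequences.
#' @param name assembly label.
#' @return an object of class `Assembly`: a list with elements `name` and
#'   `seq` (named character vector, uppercase).
#' @export
assembly <- function(seqs, name = "assembly") {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    abort("assembly: all scaffolds must be named")
  if (anyDuplicated(ids))
    abort("assembly: duplicate scaffold id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    abort("assembly: empty sequence for scaffold(s): %s",
          paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs <- vapply(seqs, normalize_seq, "", USE.NAMES = FALSE)
  names(seqs) <- ids
  structure(list(name = name, seq = seqs), class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  n <- length(x$seq)
  cat(sprintf("Assembly '%s': %d scaffold%s, %s bp total\n",
              x$name, n, if (n == 1L) "" else "s",
              format(sum(nchar(x$seq)), big.mark = ",")))
  invisible(x)
}

#' Normalize a nucleotide sequence
#'
#' Uppercases and maps IUPAC ambiguity codes (R, Y, S, W, K, M, B, D, H, V)
#' to N. Characters outside the IUPAC nucleotide alphabet raise an error.
#'
#' @param seq character scalar.
#' @return normalized character scalar over \{A,C,G,T,N\}.
#' @export
normalize_seq <- function(seq) {
  r <- charToRaw(seq)
  out <- .NORMALIZE[as.integer(r) + 1L]
  if (anyNA(out)) {
    bad <- unique(rawToChar(r[is.na(out)], multiple = TRUE))
    abort("sequence contains non-nucleotide character(s): %s",
          paste(bad, collapse = ", "))
  }
  rawToChar(as.raw(out))
}

.NORMALIZE <- local({
  m <- rep(NA_integer_, 256L)
  keep <- utf8ToInt("ACGTN")
  m[keep + 1L] <- keep
  m[utf8ToInt("acgtn") + 1L] <- keep
  amb <- "RYSWKMBDHVryswkmbdhv"
  m[utf8ToInt(amb) + 1L] <- utf8ToInt("N")
  m
})

#' Read a FASTA file into an Assembly
#'
#' @param path FASTA file (wrapped or unwrapped, uncompressed or gzip).
#' @param name assembly label; defaults to the file name without extension.
#' @return [assembly()] object; record order preserved.
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) abort("read_fasta: file not found: %s", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("read_fasta: no FASTA records in %s", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  assembly(seqs, name = name)
}

#' Write an Assembly to FASTA
#'
#' @param x Assembly.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "Assembly"))
  set <- Biostrings::BStringSet(x$seq)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Split scaffolds into contigs at long N runs
#'
#' Cuts each scaffold at every run of at least `min_gap` consecutive N bases;
#' shorter N runs are retained inside contigs. Returns 0-based half-open
#' intervals that tile the non-cut portion of each scaffold.
#'
#' @param x Assembly.
#' @param min_gap minimum N-run length treated as an assembly gap (default 10,
#'   an NCBI-style spanned-gap heuristic).
#' @return data.frame with columns `scaffold`, `start`, `end` (0-based
#'   half-open), `length`.
#' @export
split_contigs <- function(x, min_gap = 10L) {
  stopifnot(inherits(x, "Assembly"), min_gap >= 1L)
  res <- lapply(names(x$seq), function(id) {
    s <- x$seq[[id]]
    n <- nchar(s)
    gaps <- gregexpr(sprintf("N{%d,}", min_gap), s, perl = TRUE)[[1L]]
    if (gaps[1L] == -1L) {
      st <- 0L; en <- n
    } else {
      gs <- as.integer(gaps) - 1L                       # 0-based gap starts
      ge <- gs + attr(gaps, "match.length")             # 0-based gap ends
      st <- c(0L, ge)
      en <- c(gs, n)
      keep <- en > st                                   # drop empty pieces
      st <- st[keep]; en <- en[keep]
    }
    if (length(st) == 0L) return(NULL)
    data.frame(scaffold = id, start = st, end = en, length = en - st,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), length = integer())
  rownames(out) <- NULL
  out
}

#' Read a scaffold-to-chromosome map
#'
#' Two-column TSV (scaffold, chromosome), no header. Scaffolds absent from the
#' map are "unplaced". A scaffold listed twice with conflicting chromosomes is
#' an error.
#'
#' @param path TSV file.
#' @return named character vector: scaffold id -> chromosome label.
#' @export
read_chromosome_map <- function(path) {
  if (!file.exists(path)) abort("read_chromosome_map: file not found: %s", path)
  if (file.size(path) == 0L) return(setNames(character(), character()))
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) abort("read_chromosome_map: expected two columns")
  chromosome_map(setNames(tab[[2L]], tab[[1L]]))
}

#' Construct a chromosome map from a named vector
#'
#' @param x named character vector, scaffold id -> chromosome label.
#' @return deduplicated named character vector.
#' @export
chromosome_map <- function(x) {
  if (length(x) == 0L) return(setNames(character(), character()))
  ids <- names(x)
  dup <- duplicated(ids)
  if (any(dup)) {
    for (id in unique(ids[dup])) {
      if (length(unique(x[ids == id])) > 1L)
        abort("chromosome map: scaffold '%s' assigned to multiple chromosomes", id)
    }
    x <- x[!dup]
  }
  x
}

#' Write a chromosome map as TSV
#' @param map named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chromosome_map <- function(map, path) {
  write.table(data.frame(names(map), unname(map)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## chromosome label for scaffold ids ("unplaced" when absent from the map)
chrom_of <- function(scaffold, map) {
  out <- unname(map[scaffold])
  out[is.na(out)] <- "unplaced"
  out
}
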