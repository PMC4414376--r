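## CpG observed/expected depletion analysis. Genes whose gene-body CpG[O/E]
## falls below 1 are predicted to be germline-methylated (methylated CpGs
## deaminate to TpG over evolutionary time, depleting CpG dinucleotides).

## counts underlying CpG[O/E]; N bases are excluded from all counts and from L
cpg_counts <- function(seq) {
  r <- charToRaw(seq)
  list(n_cpg = count_dinucleotide(r, charToRaw("CG")),
       n_c = sum(r == as.raw(67L)),
       n_g = sum(r == as.raw(71L)),
       len = sum(r != .RAW_N))
}

#' CpG observed/expected ratio of a sequence
#'
#' `(n_CpG * L) / (n_C * n_G)` with `n_CpG` the overlapping count of "CG"
#' dinucleotides and `L` the non-N length. Undefined (NA) when the sequence
#' contains no C or no G — distinct from a ratio of 0.
#'
#' @param seq normalized sequence string, or a character vector of pieces
#'   (for example exons): counts are pooled across pieces without counting
#'   junction-spanning dinucleotides.
#' @return non-negative real, or NA when undefined.
#' @export
cpg_oe <- function(seq) {
  cs <- lapply(seq, cpg_counts)
  n_cpg <- sum(vapply(cs, `[[`, 0, "n_cpg"))
  n_c <- sum(vapply(cs, `[[`, 0, "n_c"))
  n_g <- sum(vapply(cs, `[[`, 0, "n_g"))
  len <- sum(vapply(cs, `[[`, 0, "len"))
  if (n_c == 0L || n_g == 0L) return(NA_real_)
  (n_cpg * len) / (n_c * n_g)
}

#' Read gene models from GFF3
#'
#' Understands the conventional gene -> mRNA -> exon hierarchy as well as
#' exons parented directly by genes. Coordinates are converted to the
#' package-internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return data.frame of exons: `gene`, `scaffold`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort("read_gene_models: file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  parents <- vapply(as.list(md$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, "")
  type <- as.character(md$type)
  ## map feature id -> owning gene id
  owner <- setNames(ids, ids)
  gene_ids <- ids[type == "gene"]
  for (pass in 1:2) {   # two passes resolve exon -> mRNA -> gene
    resolved <- owner[parents]
    take <- !is.na(parents) & !is.na(resolved)
    owner[take] <- resolved[take]
  }
  ex <- which(type == "exon")
  if (!length(ex)) abort("read_gene_models: no exon features in %s", path)
  gene <- owner[parents[ex]]
  gene[is.na(gene)] <- parents[ex][is.na(gene)]
  data.frame(gene = unname(gene),
             scaffold = as.character(GenomicRanges::seqnames(gr))[ex],
             start = GenomicRanges::start(gr)[ex] - 1L,
             end = GenomicRanges::end(gr)[ex],
             strand = as.character(GenomicRanges::strand(gr))[ex],
             stringsAsFactors = FALSE)
}

## region sequences per gene as lists of pieces
gene_region_seqs <- function(x, exons, region) {
  out <- list()
  for (g in unique(exons$gene)) {
    ge <- exons[exons$gene == g, , drop = FALSE]
    ge <- ge[order(ge$start), , drop = FALSE]
    scaf <- ge$scaffold[1L]
    s <- x$seq[[scaf]]
    if (is.null(s)) abort("classify_genes: scaffold '%s' (gene '%s') not in assembly", scaf, g)
    if (any(ge$start < 0L) || any(ge$end > nchar(s)))
      abort("classify_genes: feature of gene '%s' outside scaffold bounds", g)
    pieces <- switch(region,
      gene = ,
      exon = substring(s, ge$start + 1L, ge$end),
      intron = {
        if (nrow(ge) < 2L) character() else
          substring(s, head(ge$end, -1L) + 1L, tail(ge$start, -1L))
      })
    out[[g]] <- pieces
  }
  out
}

#' Predict gene methylation from CpG depletion
#'
#' Computes CpG[O/E] per gene over the chosen region and predicts a gene as
#' methylated when the ratio is below `threshold`. The default region is the
#' gene body, defined as all exons concatenated; "intron" concatenates the
#' intervals between consecutive exons. Genes with undefined O/E (no C or no
#' G, or an empty region) are never predicted methylated and are tallied
#' separately.
#'
#' @param x Assembly.
#' @param annotation GFF3 path or an exon data.frame from
#'   [read_gene_models()].
#' @param region "gene" (gene body = concatenated exons; "exon" is a
#'   synonym) or "intron".
#' @param threshold CpG[O/E] below which a gene is called methylated
#'   (default 1.0).
#' @return list of class `cpg_classification`: `results` (per-gene
#'   data.frame: `feature_id`, `class`, `length`, `n_cpg`, `n_c`, `n_g`,
#'   `cpg_oe`, `predicted_methylated`), `n_methylated`, `n_unmethylated`,
#'   `n_undefined`, `threshold`.
#' @export
classify_genes <- function(x, annotation, region = c("gene", "exon", "intron"),
                           threshold = 1.0) {
  region <- match.arg(region)
  exons <- if (is.character(annotation)) read_gene_models(annotation) else annotation
  seqs <- gene_region_seqs(x, exons, region)
  rows <- lapply(names(seqs), function(g) {
    pieces <- seqs[[g]]
    if (!length(pieces) || !any(nzchar(pieces)))
      return(data.frame(feature_id = g, class = region, length = 0L,
                        n_cpg = 0L, n_c = 0L, n_g = 0L, cpg_oe = NA_real_,
                        stringsAsFactors = FALSE))
    cs <- lapply(pieces, cpg_counts)
    n_cpg <- sum(vapply(cs, `[[`, 0, "n_cpg"))
    n_c <- sum(vapply(cs, `[[`, 0, "n_c"))
    n_g <- sum(vapply(cs, `[[`, 0, "n_g"))
    len <- sum(vapply(cs, `[[`, 0, "len"))
    oe <- if (n_c == 0L || n_g == 0L) NA_real_ else (n_cpg * len) / (n_c * n_g)
    data.frame(feature_id = g, class = region, length = len,
               n_cpg = n_cpg, n_c = n_c, n_g = n_g, cpg_oe = oe,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$predicted_methylated <- !is.na(res$cpg_oe) & res$cpg_oe < threshold
  structure(list(results = res,
                 n_methylated = sum(res$predicted_methylated),
                 n_unmethylated = sum(!res$predicted_methylated & !is.na(res$cpg_oe)),
                 n_undefined = sum(is.na(res$cpg_oe)),
                 threshold = threshold),
            class = "cpg_classification")
}

#' @export
print.cpg_classification <- function(x, ...) {
  cat(sprintf("CpG[O/E] classification (threshold %.2f): %d genes\n",
              x$threshold, nrow(x$results)))
  cat(sprintf("  predicted methylated (O/E < %.2f): %d\n",
              x$threshold, x$n_methylated))
  cat(sprintf("  not depleted: %d; undefined O/E: %d\n",
              x$n_unmethylated, x$n_undefined))
  invisible(x)
}

#' Compare CpG[O/E] across feature classes
#'
#' @param results a data.frame of per-feature results (rbind the `results`
#'   elements of several [classify_genes()] runs, e.g. gene-body vs intron).
#' @param threshold depletion threshold used for the depleted fraction.
#' @return data.frame with one row per class: n, mean/median O/E, and the
#'   fraction of defined-O/E features below the threshold.
#' @export
compare_feature_classes <- function(results, threshold = 1.0) {
  if (is.null(results) || nrow(results) == 0L)
    abort("compare_feature_classes: empty results")
  out <- lapply(split(results, results$class), function(df) {
    oe <- df$cpg_oe[!is.na(df$cpg_oe)]
    data.frame(class = df$class[1L], n = nrow(df), n_defined = length(oe),
               mean_oe = mean(oe), median_oe = median(oe),
               depleted_fraction = mean(oe < threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
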