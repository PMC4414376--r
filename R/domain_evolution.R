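## Protein-domain comparative statistics between two species: unique domains,
## Fisher-exact expansion/contraction scans, domain-arrangement clustering,
## and within-protein repeat-number comparison. Input is a per-species table
## of Pfam-style domain hits (one row per hit): gene id, domain id, envelope
## coordinates on the protein, and the covered region of the domain model.

#' Read a domain-hit table
#'
#' TSV with header and columns `gene`, `domain`, `protein_start`,
#' `protein_end`, `model_start`, `model_end`. One record per gene is assumed
#' (longest transcript only); hits are sorted by protein coordinate.
#'
#' @param path TSV file.
#' @param species species label attached to the result.
#' @return data.frame of hits sorted by (gene, protein_start), with a
#'   `species` attribute.
#' @export
read_domain_hits <- function(path, species = basename(path)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "domain", "protein_start", "protein_end",
            "model_start", "model_end")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort("read_domain_hits: missing column(s): %s", paste(miss, collapse = ", "))
  tab <- tab[order(tab$gene, tab$protein_start), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "species") <- species
  tab
}

#' Merge split hits that consecutively cover one domain model
#'
#' Two adjacent hits of the same domain within one gene are merged when the
#' second hit resumes the model region where the first left off (model-region
#' continuity within `model_tol` positions) and the hits are close on the
#' protein (gap at most `protein_gap` residues). Independent full-model
#' repeats are left as separate hits.
#'
#' @param hits domain-hit data.frame (any number of genes).
#' @param model_tol allowed slack in model-region continuity (default 10).
#' @param protein_gap maximum residue gap between the hits (default 30).
#' @return data.frame with merged rows; coordinates span the merged extent.
#' @export
collapse_consecutive <- function(hits, model_tol = 10L, protein_gap = 30L) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$gene, hits$protein_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits) - 1L)) {
    if (!keep[i]) next
    j <- i + 1L
    if (hits$gene[j] != hits$gene[i] || hits$domain[j] != hits$domain[i]) next
    model_cont <- abs(hits$model_start[j] - hits$model_end[i]) <= model_tol &&
      hits$model_start[j] > hits$model_start[i]
    adjacent <- hits$protein_start[j] - hits$protein_end[i] <= protein_gap
    if (model_cont && adjacent) {
      hits$protein_end[i] <- hits$protein_end[j]
      hits$model_end[i] <- hits$model_end[j]
      keep[j] <- FALSE
      ## allow chains of more than two split hits
      hits$gene[j] <- hits$gene[i]; hits$domain[j] <- hits$domain[i]
      hits[j, c("protein_start", "protein_end", "model_start", "model_end")] <-
        hits[i, c("protein_start", "protein_end", "model_start", "model_end")]
      keep[i] <- FALSE; keep[j] <- TRUE
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count genes containing each domain
#'
#' Every domain is counted once per gene in which it appears, regardless of
#' copy number.
#'
#' @param hits domain-hit data.frame (collapse split hits first).
#' @return named integer vector: domain id -> gene count.
#' @export
count_domains <- function(hits) {
  if (nrow(hits) == 0L) return(setNames(integer(), character()))
  u <- unique(hits[, c("gene", "domain")])
  tab <- table(u$domain)
  setNames(as.integer(tab), names(tab))
}

#' Domains unique to a focal species
#'
#' @param focal named count vector (from [count_domains()]).
#' @param refs list of reference count vectors (at least one).
#' @return character vector of domain ids present in the focal species and in
#'   no reference species.
#' @export
unique_domains <- function(focal, refs) {
  if (!is.list(refs) || length(refs) == 0L)
    abort("unique_domains: at least one reference species is required")
  present <- names(focal)[focal > 0L]
  ref_present <- unique(unlist(lapply(refs, function(r) names(r)[r > 0L])))
  setdiff(present, ref_present)
}

#' Two-sided Fisher's exact test for a domain occurrence contrast
#'
#' Tests the 2x2 table `[[count_focal, total_focal - count_focal],
#' [count_ref, total_ref - count_ref]]`; the two-sided P value sums all
#' tables with point probability at most that of the observed table.
#'
#' @param count_focal,total_focal occurrences and total in the focal species.
#' @param count_ref,total_ref occurrences and total in the reference species.
#' @return two-sided P value.
#' @export
fisher_expansion_test <- function(count_focal, total_focal,
                                  count_ref, total_ref) {
  if (total_focal <= 0L || total_ref <= 0L)
    abort("fisher_expansion_test: totals must be positive")
  if (count_focal > total_focal || count_ref > total_ref)
    abort("fisher_expansion_test: counts exceed totals")
  m <- matrix(c(count_focal, total_focal - count_focal,
                count_ref, total_ref - count_ref),
              nrow = 2L, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Scan all domains for expansions/contractions between two species
#'
#' Each domain present in either species is tested with Fisher's exact test
#' on its occurrence count against the total occurrences in each species
#' (once-per-gene counting). P values are reported raw, without multiplicity
#' correction, unless `adjust` names a [stats::p.adjust()] method.
#'
#' @param focal,ref named count vectors from [count_domains()].
#' @param alpha significance threshold (default 0.05).
#' @param adjust optional multiple-testing correction method (default none).
#' @return data.frame with one row per flagged domain: counts, totals, `p`,
#'   and `direction` ("expanded"/"contracted" in the focal species). The full
#'   table of all tested domains is attached as attribute `"all"`.
#' @export
scan_expansions <- function(focal, ref, alpha = 0.05, adjust = "none") {
  if (length(focal) == 0L || length(ref) == 0L)
    abort("scan_expansions: both count tables must be non-empty")
  domains <- union(names(focal), names(ref))
  cf <- ifelse(domains %in% names(focal), focal[domains], 0L)
  cr <- ifelse(domains %in% names(ref), ref[domains], 0L)
  tf <- sum(focal); tr <- sum(ref)
  p <- vapply(seq_along(domains), function(i)
    fisher_expansion_test(cf[i], tf, cr[i], tr), numeric(1L))
  p_adj <- stats::p.adjust(p, method = adjust)
  all_tab <- data.frame(domain = domains,
                        count_focal = as.integer(cf), total_focal = tf,
                        count_ref = as.integer(cr), total_ref = tr,
                        p = p_adj,
                        direction = ifelse(cf / tf >= cr / tr,
                                           "expanded", "contracted"),
                        stringsAsFactors = FALSE)
  out <- all_tab[all_tab$p < alpha, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  out
}

## arrangement label of a protein: sorted distinct domain set
arrangement_of <- function(domains) paste(sort(unique(domains)), collapse = "+")

#' Compare within-protein domain repeat numbers between two species
#'
#' Proteins are clustered by domain arrangement (the set of distinct domains,
#' ignoring copy number and order). Arrangements present in both species and
#' occurring at least twice in at least one species are analyzed: for each
#' member domain, the minimal and maximal per-protein repeat count is
#' computed per species, and domains whose ranges do not overlap between the
#' species are flagged.
#'
#' @param hits1,hits2 collapsed domain-hit data.frames for the two species.
#' @return data.frame: `arrangement`, `domain`, per-species `min`/`max`
#'   repeat counts, per-species arrangement occurrence counts, and `disjoint`
#'   (TRUE where the ranges do not overlap).
#' @export
compare_repeat_numbers <- function(hits1, hits2) {
  per_protein <- function(hits) {
    if (nrow(hits) == 0L)
      return(data.frame(gene = character(), arrangement = character(),
                        domain = character(), n = integer()))
    cnt <- as.data.frame(table(gene = hits$gene, domain = hits$domain),
                         stringsAsFactors = FALSE)
    cnt <- cnt[cnt$Freq > 0L, , drop = FALSE]
    arr <- tapply(hits$domain, hits$gene, arrangement_of)
    cnt$arrangement <- unname(arr[cnt$gene])
    data.frame(gene = cnt$gene, arrangement = cnt$arrangement,
               domain = cnt$domain, n = cnt$Freq, stringsAsFactors = FALSE)
  }
  p1 <- per_protein(hits1)
  p2 <- per_protein(hits2)
  occ1 <- tapply(p1$gene, p1$arrangement, function(g) length(unique(g)))
  occ2 <- tapply(p2$gene, p2$arrangement, function(g) length(unique(g)))
  shared <- intersect(names(occ1), names(occ2))
  shared <- shared[pmax(occ1[shared], occ2[shared]) >= 2L]
  res <- lapply(shared, function(a) {
    d1 <- p1[p1$arrangement == a, , drop = FALSE]
    d2 <- p2[p2$arrangement == a, , drop = FALSE]
    doms <- sort(unique(c(d1$domain, d2$domain)))
    do.call(rbind, lapply(doms, function(dm) {
      n1 <- d1$n[d1$domain == dm]
      n2 <- d2$n[d2$domain == dm]
      if (!length(n1)) n1 <- 0L
      if (!length(n2)) n2 <- 0L
      data.frame(arrangement = a, domain = dm,
                 min1 = min(n1), max1 = max(n1),
                 min2 = min(n2), max2 = max(n2),
                 occ1 = unname(occ1[a]), occ2 = unname(occ2[a]),
                 disjoint = min(n1) > max(n2) || min(n2) > max(n1),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(arrangement = character(), domain = character(),
                      min1 = integer(), max1 = integer(),
                      min2 = integer(), max2 = integer(),
                      occ1 = integer(), occ2 = integer(),
                      disjoint = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
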