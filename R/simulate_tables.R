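## Generators for the domain-evolution and CpG analyses: two-species domain
## annotation tables with implanted expansions/contractions and repeat-number
## shifts, and two-class gene sequence sets with controlled CpG[O/E].

#' Simulate two-species domain-annotation tables
#'
#' Both species draw genes from the same domain-occurrence distribution
#' (shared weights), so the null hypothesis of equal occurrence proportions
#' holds exactly for every domain unless an effect is implanted. Per-domain
#' within-protein repeat counts are conserved between species under the null;
#' `repeat_shift` effects change them in the focal species only.
#'
#' Effects are lists: `list(type = "expansion", domain = "D001", fold = 3)`
#' multiplies the focal species' gene count for the domain (fold < 1 gives a
#' contraction); `list(type = "repeat_shift", domain = "D002", delta = 2)`
#' adds `delta` to the focal species' repeat count for every gene carrying
#' the domain.
#'
#' @param n_genes genes per species.
#' @param n_domains size of the domain universe.
#' @param effects list of implanted effects (default none: a null
#'   simulation).
#' @param multi_domain_frac fraction of genes carrying two domains (the rest
#'   carry one); multi-domain genes create shared arrangements.
#' @param repeat_lambda Poisson mean of the conserved per-domain repeat
#'   excess over 1.
#' @param seed RNG seed.
#' @return list: `focal`, `ref` (hit data.frames as [read_domain_hits()]),
#'   and `truth` (the effect list).
#' @export
simulate_domain_tables <- function(n_genes = 5000L, n_domains = 500L,
                                   effects = list(),
                                   multi_domain_frac = 0.3,
                                   repeat_lambda = 0.4,
                                   seed = 1L) {
  set.seed(seed)
  dom_ids <- sprintf("D%03d", seq_len(n_domains))
  w <- rexp(n_domains) + 0.2           # shared occurrence weights
  w <- w / sum(w)
  base_repeat <- setNames(1L + rpois(n_domains, repeat_lambda), dom_ids)

  gen_species <- function(species, extra_genes = NULL, repeat_delta = NULL) {
    n_dom_per_gene <- 1L + rbinom(n_genes, 1L, multi_domain_frac)
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      doms <- dom_ids[sample.int(n_domains, n_dom_per_gene[g], prob = w)]
      reps <- base_repeat[doms]
      if (!is.null(repeat_delta)) {
        hit <- doms %in% names(repeat_delta)
        reps[hit] <- pmax(1L, reps[hit] + repeat_delta[doms[hit]])
      }
      rows[[g]] <- data.frame(gene = sprintf("%s_g%05d", species, g),
                              domain = rep(doms, reps),
                              stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, c(rows, extra_genes))
    ## lay hits along each protein: 80-residue domains, 5-residue gaps,
    ## full model coverage
    ord <- order(hits$gene)
    hits <- hits[ord, , drop = FALSE]
    idx <- unlist(lapply(rle(hits$gene)$lengths, seq_len))
    hits$protein_start <- (idx - 1L) * 85L + 1L
    hits$protein_end <- hits$protein_start + 79L
    hits$model_start <- 1L
    hits$model_end <- 80L
    rownames(hits) <- NULL
    attr(hits, "species") <- species
    hits
  }

  repeat_delta <- NULL
  for (e in effects) {
    if (e$type == "repeat_shift") {
      repeat_delta <- c(repeat_delta, setNames(as.integer(e$delta), e$domain))
    }
  }
  focal <- gen_species("sp1", repeat_delta = repeat_delta)
  ref <- gen_species("sp2")
  for (e in effects) {
    if (e$type != "expansion") next
    carriers <- unique(focal$gene[focal$domain == e$domain])
    n_cur <- length(carriers)
    n_new <- round(n_cur * e$fold)
    if (n_new > n_cur) {
      add <- lapply(seq_len(n_new - n_cur), function(i)
        data.frame(gene = sprintf("sp1_x%s_%03d", e$domain, i),
                   domain = e$domain, protein_start = 1L, protein_end = 80L,
                   model_start = 1L, model_end = 80L, stringsAsFactors = FALSE))
      focal <- rbind(focal, do.call(rbind, add))
    } else if (n_new < n_cur) {
      drop <- carriers[seq_len(n_cur - n_new)]
      focal <- focal[!(focal$gene %in% drop), , drop = FALSE]
    }
  }
  focal <- focal[order(focal$gene, focal$protein_start), , drop = FALSE]
  rownames(focal) <- NULL
  attr(focal, "species") <- "sp1"
  list(focal = focal, ref = ref, truth = effects)
}

## one gene sequence with realized CpG[O/E] steered to the target by CG
## swap moves that conserve base composition
tune_gene_cpg <- function(len, target, gc, tol = 0.015, max_iter = 400L) {
  r <- gen_background(len, gc)
  C <- as.raw(67L); G <- as.raw(71L)
  for (iter in seq_len(max_iter)) {
    ncg <- count_dinucleotide(r, charToRaw("CG"))
    nc <- sum(r == C); ng <- sum(r == G)
    oe <- ncg * len / (nc * ng)
    want <- round(target * nc * ng / len)
    if (abs(oe - target) <= tol || want == ncg) break
    if (want < ncg) {
      ## break one CpG: swap its G with a random A/T elsewhere
      cg_at <- which(r[-len] == C & r[-1L] == G)
      i <- cg_at[sample.int(length(cg_at), 1L)] + 1L     # the G
      at <- which(r != C & r != G)
      at <- at[at > 1L & at < len]
      at <- at[r[pmax(at - 1L, 1L)] != C]                # no new CpG there
      if (!length(at)) break
      j <- at[sample.int(length(at), 1L)]
      tmp <- r[i]; r[i] <- r[j]; r[j] <- tmp
    } else {
      ## create one CpG: move a non-CpG G behind a C without a G
      c_open <- which(r[-len] == C & r[-1L] != G & r[-1L] != C)
      g_free <- which(r == G)
      g_free <- g_free[g_free > 1L & g_free < len]
      g_free <- g_free[r[g_free - 1L] != C]              # not part of a CpG
      if (!length(c_open) || !length(g_free)) break
      i <- c_open[sample.int(length(c_open), 1L)] + 1L   # target slot
      j <- g_free[sample.int(length(g_free), 1L)]
      if (i == j || abs(i - j) == 1L) next
      tmp <- r[i]; r[i] <- r[j]; r[j] <- tmp
    }
  }
  rawToChar(r)
}

#' Simulate a two-class methylome gene set
#'
#' Gene sequences are generated per class with realized CpG[O/E] steered
#' close to the class target (composition-preserving CG swap moves), so the
#' class structure is sharp relative to the classification threshold.
#'
#' @param n_genes number of genes.
#' @param class_props class proportions (depleted first); must sum to 1.
#' @param targets per-class CpG[O/E] targets.
#' @param gene_len gene length in bp.
#' @param gc GC content.
#' @param seed RNG seed.
#' @return list: `genes` (named character vector), `labels` (class index per
#'   gene, 1 = depleted), `targets`.
#' @export
simulate_methylome <- function(n_genes = 2000L,
                               class_props = c(0.5, 0.5),
                               targets = c(0.65, 1.05),
                               gene_len = 2000L,
                               gc = 0.40,
                               seed = 1L) {
  stopifnot(length(class_props) == length(targets),
            abs(sum(class_props) - 1) < 1e-8)
  upper <- gene_len / (gc * gene_len / 2)   # loose attainability bound
  if (any(targets >= upper))
    abort("simulate_methylome: target O/E %.2f not attainable at this GC",
          max(targets))
  set.seed(seed)
  labels <- rep(seq_along(class_props), times = round(n_genes * class_props))
  labels <- sample(c(labels, rep(length(class_props),
                                 max(0L, n_genes - length(labels))))[seq_len(n_genes)])
  genes <- vapply(seq_len(n_genes), function(i)
    tune_gene_cpg(gene_len, targets[labels[i]], gc), "")
  names(genes) <- sprintf("gene%04d", seq_len(n_genes))
  list(genes = genes, labels = labels, targets = targets)
}
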