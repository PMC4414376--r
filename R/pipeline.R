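## End-to-end orchestration: SSR scan -> flank matching -> synteny map ->
## rearrangement classification, plus evaluation of a run against a
## simulation's truth tables, and a config-driven entry point.

#' Run the full synteny analysis on two assemblies
#'
#' @param assembly_a reference Assembly.
#' @param assembly_b partner Assembly.
#' @param chrom_map_a,chrom_map_b scaffold-to-chromosome maps (named
#'   character vectors); missing scaffolds are "unplaced".
#' @param ssr [ssr_params()].
#' @param match [match_params()].
#' @param synteny [synteny_params()].
#' @return list of class `synteny_analysis`: `ssrs_a`, `ssrs_b`, `pairs`,
#'   `markers` (with block assignment), `blocks`, `links`, `events`,
#'   `summary`.
#' @export
run_synteny_analysis <- function(assembly_a, assembly_b,
                                 chrom_map_a = character(),
                                 chrom_map_b = character(),
                                 ssr = ssr_params(),
                                 match = match_params(),
                                 synteny = synteny_params()) {
  ssrs_a <- extract_flanks(find_assembly_ssrs(assembly_a, ssr), assembly_a, ssr)
  ssrs_b <- extract_flanks(find_assembly_ssrs(assembly_b, ssr), assembly_b, ssr)
  pairs <- match_markers(ssrs_a, ssrs_b, match)
  tracks <- build_tracks(pairs, chrom_map_a, chrom_map_b)
  built <- build_blocks(tracks, synteny)
  blocks <- place_unplaced(built$blocks, built$markers, synteny)
  links <- link_scaffolds(blocks)
  events <- classify_rearrangements(blocks)
  summary <- summarize_synteny(blocks, events, assembly_a, assembly_b, synteny)
  structure(list(ssrs_a = ssrs_a, ssrs_b = ssrs_b, pairs = pairs,
                 markers = built$markers, blocks = blocks, links = links,
                 events = events, summary = summary),
            class = "synteny_analysis")
}

#' Evaluate marker matching against simulation truth
#'
#' Recall is the fraction of implanted homologous pairs recovered (a truth
#' pair counts as recovered when some reported pair overlaps its interval on
#' both assemblies). Precision is the fraction of reported pairs that are
#' consistent with the true homology map: both loci trace back to ancestor
#' positions within `tol` bp of each other on the same ancestor chromosome
#' (this also credits correctly matched background loci that arose in the
#' ancestor sequence by chance).
#'
#' @param pairs reported pairs from [match_markers()].
#' @param sim an `ssr_simulation` from [simulate_assembly_pair()].
#' @param tol ancestor-coordinate tolerance in bp.
#' @return list with `recall`, `precision`, `n_reported`, `n_truth`.
#' @export
evaluate_matches <- function(pairs, sim, tol = 100L) {
  truth <- sim$pairs
  n_truth <- nrow(truth)
  recovered <- logical(n_truth)
  if (nrow(pairs)) {
    key_a <- paste(pairs$scaffold_a)
    for (i in seq_len(n_truth)) {
      hit <- pairs$scaffold_a == truth$scaffold_a[i] &
        pairs$start_a < truth$end_a[i] & pairs$end_a > truth$start_a[i] &
        pairs$scaffold_b == truth$scaffold_b[i] &
        pairs$start_b < truth$end_b[i] & pairs$end_b > truth$start_b[i]
      recovered[i] <- any(hit)
    }
  }
  correct <- logical(nrow(pairs))
  if (nrow(pairs)) {
    mid_a <- (pairs$start_a + pairs$end_a) %/% 2L
    mid_b <- (pairs$start_b + pairs$end_b) %/% 2L
    anc_a <- unlift_position(sim$a, pairs$scaffold_a, mid_a)
    anc_b <- unlift_position(sim$b, pairs$scaffold_b, mid_b)
    correct <- anc_a$anc_chrom == anc_b$anc_chrom &
      abs(anc_a$anc_pos - anc_b$anc_pos) <= tol
  }
  list(recall = if (n_truth) mean(recovered) else NA_real_,
       precision = if (nrow(pairs)) mean(correct) else NA_real_,
       n_reported = nrow(pairs), n_truth = n_truth)
}

#' Evaluate detected rearrangements against simulation truth
#'
#' Checks the intra/inter event counts against the implanted history and, for
#' each true event, whether a detected event of the right type on the right
#' reference scaffold has a breakpoint interval containing the true
#' breakpoint (detected breakpoint intervals span the gap between the
#' flanking markers, so a correct call localizes the break to one
#' inter-marker interval).
#'
#' @param events detected events from [classify_rearrangements()].
#' @param sim an `ssr_simulation`.
#' @param slack bp slack added to each breakpoint interval (covers indel
#'   drift between the assemblies).
#' @return list: `n_intra`, `n_inter`, `true_intra`, `true_inter`,
#'   `counts_match`, `breakpoint_hits` (fraction of true events whose
#'   breakpoints are localized), `matched` (logical per true event).
#' @export
evaluate_events <- function(events, sim, slack = 200L) {
  truth <- sim$events
  true_intra <- sum(truth$type == "inversion")
  true_inter <- sum(truth$type == "translocation")
  n_intra <- sum(events$type == "intra")
  n_inter <- sum(events$type == "inter")
  matched <- logical(nrow(truth))
  if (!is.null(truth) && nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      want_type <- if (truth$type[i] == "inversion") "intra" else "inter"
      cand <- events[events$type == want_type &
                     events$ref_scaffold == truth$ref_scaffold[i], , drop = FALSE]
      if (!nrow(cand)) next
      ok <- FALSE
      for (j in seq_len(nrow(cand))) {
        b1 <- c(cand$bp1_start[j], cand$bp1_end[j])
        b2 <- c(cand$bp2_start[j], cand$bp2_end[j])
        in1 <- function(x, b) !is.na(b[2L]) &&
          x >= (if (is.na(b[1L])) -Inf else b[1L]) - slack && x <= b[2L] + slack
        in2 <- function(x, b) !is.na(b[1L]) &&
          x >= b[1L] - slack && x <= (if (is.na(b[2L])) Inf else b[2L]) + slack
        hit_start <- in1(truth$ref_start[i], b1) || in2(truth$ref_start[i], b2)
        hit_end <- in1(truth$ref_end[i], b1) || in2(truth$ref_end[i], b2)
        if (hit_start && hit_end) { ok <- TRUE; break }
      }
      matched[i] <- ok
    }
  }
  list(n_intra = n_intra, n_inter = n_inter,
       true_intra = true_intra, true_inter = true_inter,
       counts_match = n_intra == true_intra && n_inter == true_inter,
       breakpoint_hits = if (length(matched)) mean(matched) else NA_real_,
       matched = matched)
}

.CONFIG_KEYS <- list(
  top = c("fasta_a", "fasta_b", "name_a", "name_b", "chrom_map_a",
          "chrom_map_b", "out_dir", "ssr", "match", "synteny"),
  ssr = c("min_units", "motif_lengths", "flank_len", "min_flank_total"),
  match = c("min_identity", "min_aligned_fraction", "require_same_motif",
            "tie_margin", "match", "mismatch", "gap_open", "gap_extend",
            "kmer_len", "min_shared_kmers"),
  synteny = c("max_singleton_ignore", "min_break_support",
              "min_placement_support", "large_block_threshold"))

check_keys <- function(cfg, section, allowed) {
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    abort("config: unknown key(s) in %s: %s", section,
          paste(unknown, collapse = ", "))
}

#' Run the configured pipeline and write its outputs
#'
#' Reads a YAML configuration (or an equivalent named list), runs
#' [run_synteny_analysis()], and writes blocks/pairs/events/links TSVs, BED
#' tracks for both assemblies' block coordinates, a JSON summary, and an echo
#' of the effective configuration. Unknown configuration keys are an error.
#'
#' @param config path to a YAML file or a named list.
#' @return the `synteny_analysis` object, invisibly; outputs land in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys(cfg, "top level", .CONFIG_KEYS$top)
  for (sec in c("ssr", "match", "synteny"))
    if (!is.null(cfg[[sec]])) check_keys(cfg[[sec]], sec, .CONFIG_KEYS[[sec]])
  for (f in c("fasta_a", "fasta_b")) {
    if (is.null(cfg[[f]])) abort("config: '%s' is required", f)
    if (!file.exists(cfg[[f]])) abort("config: input not found: %s", cfg[[f]])
  }
  out_dir <- cfg$out_dir %||% "microsynt_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- read_fasta(cfg$fasta_a, name = cfg$name_a %||% "A")
  b <- read_fasta(cfg$fasta_b, name = cfg$name_b %||% "B")
  map_a <- if (!is.null(cfg$chrom_map_a)) read_chromosome_map(cfg$chrom_map_a)
           else character()
  map_b <- if (!is.null(cfg$chrom_map_b)) read_chromosome_map(cfg$chrom_map_b)
           else character()
  res <- run_synteny_analysis(
    a, b, map_a, map_b,
    ssr = do.call(ssr_params, cfg$ssr %||% list()),
    match = do.call(match_params, cfg$match %||% list()),
    synteny = do.call(synteny_params, cfg$synteny %||% list()))

  tsv <- function(df, name) write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(res$pairs, "pairs.tsv")
  tsv(res$blocks, "blocks.tsv")
  tsv(res$events, "events.tsv")
  tsv(res$links, "links.tsv")
  write_ssr_bed(res$blocks[, c("ref_scaffold", "ref_start", "ref_end")] |>
                  stats::setNames(c("scaffold", "start", "end")) |>
                  transform(motif = "block", n_units = res$blocks$block_id),
                file.path(out_dir, "blocks_ref.bed"))
  write_ssr_bed(res$blocks[, c("partner_scaffold", "partner_start",
                               "partner_end")] |>
                  stats::setNames(c("scaffold", "start", "end")) |>
                  transform(motif = "block", n_units = res$blocks$block_id),
                file.path(out_dir, "blocks_partner.bed"))
  s <- res$summary
  jsonlite::write_json(list(
    n_blocks = s$n_blocks,
    block_length_ref = s$ref, block_length_partner = s$partner,
    n_ref_scaffolds_covered = s$n_ref_scaffolds_covered,
    coverage_ref = s$coverage_ref, coverage_partner = s$coverage_partner,
    n_large_blocks = s$n_large_blocks,
    n_intra = s$n_intra, n_inter = s$n_inter,
    n_ignored_markers = sum(res$markers$status == "ignored")),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(cfg, file.path(out_dir, "config_used.yaml"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
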