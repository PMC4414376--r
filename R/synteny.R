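## Synteny-block construction from ordered homologous markers, scaffold
## linking, placement of unplaced scaffolds, and rearrangement classification.
## One assembly acts as the reference: markers are ordered along reference
## scaffolds, and blocks are maximal runs whose partner scaffold, orientation,
## and partner-coordinate direction are consistent. Short discordant runs
## (isolated loci out of order or pointing at a different scaffold) are
## ignored rather than breaking a block.

#' Synteny chaining parameters
#'
#' @param max_singleton_ignore longest run of discordant loci that is skipped
#'   without breaking a block (the "single loci are ignored" rule).
#' @param min_break_support number of consecutive discordant loci that
#'   terminates a block; must exceed `max_singleton_ignore`.
#' @param min_placement_support consecutive loci required to place an
#'   unplaced scaffold ("several consecutive loci").
#' @param large_block_threshold block span counted as "large" in summaries.
#' @return list of class `synteny_params`.
#' @export
synteny_params <- function(max_singleton_ignore = 1L,
                           min_break_support = 2L,
                           min_placement_support = 3L,
                           large_block_threshold = 5e6) {
  if (min_break_support <= max_singleton_ignore)
    abort("synteny_params: min_break_support must exceed max_singleton_ignore")
  structure(list(max_singleton_ignore = as.integer(max_singleton_ignore),
                 min_break_support = as.integer(min_break_support),
                 min_placement_support = as.integer(min_placement_support),
                 large_block_threshold = large_block_threshold),
            class = "synteny_params")
}

#' Order marker pairs into per-reference-scaffold tracks
#'
#' @param pairs data.frame from [match_markers()].
#' @param chrom_map_ref,chrom_map_partner named vectors (scaffold ->
#'   chromosome); scaffolds absent from a map are "unplaced".
#' @return data.frame of markers sorted by (reference scaffold, reference
#'   coordinate), with `ref_chrom` and `partner_chrom` annotations.
#' @export
build_tracks <- function(pairs, chrom_map_ref = character(),
                         chrom_map_partner = character()) {
  tr <- pairs[order(pairs$scaffold_a, pairs$start_a), , drop = FALSE]
  tr$ref_chrom <- chrom_of(tr$scaffold_a, chrom_map_ref)
  tr$partner_chrom <- chrom_of(tr$scaffold_b, chrom_map_partner)
  rownames(tr) <- NULL
  tr
}

## chain one track (markers of one reference scaffold, sorted by ref coord)
chain_track <- function(tr, params) {
  n <- nrow(tr)
  status <- rep("ignored", n)
  block_id <- rep(NA_integer_, n)
  blocks <- list()
  i <- 1L
  bid <- 0L
  while (i <= n) {
    ps <- tr$scaffold_b[i]; o <- tr$orientation[i]
    d <- if (o == "+") 1L else -1L
    members <- i
    last <- tr$start_b[i]
    pending <- integer()
    j <- i + 1L
    while (j <= n) {
      conc <- tr$scaffold_b[j] == ps && tr$orientation[j] == o &&
        (tr$start_b[j] - last) * d > 0L
      if (conc) {
        if (length(pending) > params$max_singleton_ignore) break
        members <- c(members, j)
        last <- tr$start_b[j]
        pending <- integer()
        j <- j + 1L
      } else {
        pending <- c(pending, j)
        if (length(pending) >= params$min_break_support) break
        j <- j + 1L
      }
    }
    if (length(members) >= 2L) {
      bid <- bid + 1L
      status[members] <- "used"
      block_id[members] <- bid
      pc <- c(tr$start_b[members], tr$end_b[members])
      blocks[[bid]] <- data.frame(
        ref_scaffold = tr$scaffold_a[i],
        ref_start = tr$start_a[members[1L]],
        ref_end = tr$end_a[members[length(members)]],
        partner_scaffold = ps,
        partner_start = min(pc),
        partner_end = max(pc),
        orientation = o,
        n_markers = length(members),
        ref_chrom = tr$ref_chrom[i],
        partner_chrom = tr$partner_chrom[i],
        stringsAsFactors = FALSE)
    }
    if (length(pending) > params$max_singleton_ignore) {
      i <- pending[1L]
    } else {
      i <- j
    }
  }
  list(blocks = do.call(rbind, blocks), status = status, block_id = block_id)
}

#' Chain ordered markers into synteny blocks
#'
#' Greedy left-to-right chaining per reference scaffold. A block extends while
#' the next marker keeps the same partner scaffold and orientation and its
#' partner coordinate is monotone (increasing for "+", decreasing for "-").
#' A discordant run of length at most `max_singleton_ignore` is marked
#' ignored and skipped; a run of `min_break_support` or more ends the block.
#' Blocks with fewer than 2 markers are discarded and their markers ignored.
#'
#' @param tracks data.frame from [build_tracks()].
#' @param params [synteny_params()].
#' @return list with `blocks` (one row per block, `block_id` assigned in
#'   reference order) and `markers` (the input with `status` used/ignored and
#'   `block_id`).
#' @export
build_blocks <- function(tracks, params = synteny_params()) {
  empty <- data.frame(ref_scaffold = character(), ref_start = integer(),
                      ref_end = integer(), partner_scaffold = character(),
                      partner_start = integer(), partner_end = integer(),
                      orientation = character(), n_markers = integer(),
                      ref_chrom = character(), partner_chrom = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tracks) == 0L)
    return(list(blocks = cbind(empty, block_id = integer()),
                markers = cbind(tracks, status = character(),
                                block_id = integer())))
  tracks$status <- NA_character_
  tracks$block_id <- NA_integer_
  all_blocks <- list()
  offset <- 0L
  for (scaf in unique(tracks$scaffold_a)) {
    sel <- which(tracks$scaffold_a == scaf)
    res <- chain_track(tracks[sel, , drop = FALSE], params)
    tracks$status[sel] <- res$status
    tracks$block_id[sel] <- res$block_id + offset
    if (!is.null(res$blocks)) {
      res$blocks$block_id <- seq_len(nrow(res$blocks)) + offset
      offset <- offset + nrow(res$blocks)
      all_blocks[[length(all_blocks) + 1L]] <- res$blocks
    }
  }
  blocks <- if (length(all_blocks)) do.call(rbind, all_blocks) else
    cbind(empty, block_id = integer())
  rownames(blocks) <- NULL
  list(blocks = blocks, markers = tracks)
}

#' Classify rearrangements from block adjacencies
#'
#' Within each reference scaffold, blocks are grouped into maximal runs by
#' partner chromosome. Runs on a chromosome other than the scaffold's
#' majority partner chromosome are counted as one inter-chromosomal event
#' each (a translocated segment is one event even though it creates two
#' boundaries). Within same-chromosome, same-partner-scaffold stretches,
#' maximal runs of minority orientation count as one intra-chromosomal event
#' each (an inversion is one event), and an out-of-order coordinate jump
#' between same-orientation neighbours is also an intra event. Boundaries
#' where only the partner scaffold changes are treated as assembly breaks,
#' not events; blocks whose partner chromosome is "unplaced" are excluded.
#'
#' @param blocks block data.frame from [build_blocks()].
#' @return data.frame of events: `type` ("intra"/"inter"), reference scaffold
#'   and chromosome, partner chromosome of the discordant segment, supporting
#'   marker count, and up to two reference breakpoint intervals
#'   (`bp1_start`..`bp1_end`, `bp2_start`..`bp2_end`; NA at scaffold ends).
#' @export
classify_rearrangements <- function(blocks) {
  empty <- data.frame(type = character(), ref_scaffold = character(),
                      ref_chrom = character(), partner_chrom = character(),
                      n_markers = integer(),
                      bp1_start = numeric(), bp1_end = numeric(),
                      bp2_start = numeric(), bp2_end = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(blocks) == 0L) return(empty)
  events <- list()
  add_event <- function(type, bs, from, to) {
    ## breakpoint intervals from flanking blocks (NA at scaffold ends)
    events[[length(events) + 1L]] <<- data.frame(
      type = type,
      ref_scaffold = bs$ref_scaffold[from],
      ref_chrom = bs$ref_chrom[from],
      partner_chrom = bs$partner_chrom[from],
      n_markers = sum(bs$n_markers[from:to]),
      bp1_start = if (from > 1L) bs$ref_end[from - 1L] else NA_real_,
      bp1_end = bs$ref_start[from],
      bp2_start = bs$ref_end[to],
      bp2_end = if (to < nrow(bs)) bs$ref_start[to + 1L] else NA_real_,
      stringsAsFactors = FALSE)
  }
  for (scaf in unique(blocks$ref_scaffold)) {
    bs <- blocks[blocks$ref_scaffold == scaf, , drop = FALSE]
    bs <- bs[order(bs$ref_start), , drop = FALSE]
    bs <- bs[bs$partner_chrom != "unplaced", , drop = FALSE]
    if (nrow(bs) < 2L) next
    ## inter: maximal partner-chromosome runs differing from the majority
    counts <- tapply(bs$n_markers, bs$partner_chrom, sum)
    background <- names(counts)[which.max(counts)]
    rl <- rle(bs$partner_chrom)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (r in seq_along(rl$values)) {
      if (rl$values[r] != background)
        add_event("inter", bs, starts[r], ends[r])
    }
    ## intra: within background-chromosome, same-partner-scaffold stretches
    bg <- bs[bs$partner_chrom == background, , drop = FALSE]
    if (nrow(bg) < 2L) next
    srl <- rle(bg$partner_scaffold)
    sends <- cumsum(srl$lengths)
    sstarts <- sends - srl$lengths + 1L
    for (r in seq_along(srl$values)) {
      seg <- bg[sstarts[r]:sends[r], , drop = FALSE]
      if (nrow(seg) < 2L) next
      ocnt <- tapply(seg$n_markers, seg$orientation, sum)
      obg <- names(ocnt)[which.max(ocnt)]
      orl <- rle(seg$orientation)
      oends <- cumsum(orl$lengths)
      ostarts <- oends - orl$lengths + 1L
      for (q in seq_along(orl$values)) {
        if (orl$values[q] != obg) {
          from <- sstarts[r] + ostarts[q] - 1L
          to <- sstarts[r] + oends[q] - 1L
          add_event("intra",
                    bg, from, to)
        }
      }
      ## same-orientation order discontinuities (transposition signal)
      for (q in seq_len(nrow(seg) - 1L)) {
        if (seg$orientation[q] != seg$orientation[q + 1L]) next
        ok <- if (seg$orientation[q] == "+")
          seg$partner_start[q + 1L] >= seg$partner_end[q]
        else
          seg$partner_end[q + 1L] <= seg$partner_start[q]
        if (!ok) {
          from <- sstarts[r] + q - 1L
          add_event("intra", bg, from + 1L, from + 1L)
        }
      }
    }
  }
  out <- if (length(events)) do.call(rbind, events) else empty
  rownames(out) <- NULL
  out
}

#' Link reference scaffolds bridged by one partner scaffold
#'
#' Two reference scaffolds are linked when a single partner scaffold carries
#' the terminal block of one and the terminal block of the other, with the
#' two terminal marker runs adjacent (no other block of that partner scaffold
#' between them). Each reference scaffold end participates in at most one
#' link; conflicts keep the link with more supporting markers.
#'
#' @param blocks block data.frame from [build_blocks()].
#' @return data.frame of links: the two reference scaffolds and ends
#'   ("start"/"end"), the bridging partner scaffold, supporting marker count,
#'   and a `conflict` flag marking links that beat a competing proposal.
#' @export
link_scaffolds <- function(blocks) {
  empty <- data.frame(ref_a = character(), end_a = character(),
                      ref_b = character(), end_b = character(),
                      partner_scaffold = character(), support = integer(),
                      conflict = logical(), stringsAsFactors = FALSE)
  if (nrow(blocks) == 0L) return(empty)
  ## terminal blocks per reference scaffold
  term <- do.call(rbind, lapply(unique(blocks$ref_scaffold), function(scaf) {
    bs <- blocks[blocks$ref_scaffold == scaf, , drop = FALSE]
    bs <- bs[order(bs$ref_start), , drop = FALSE]
    rbind(cbind(bs[1L, , drop = FALSE], ref_end_side = "start"),
          cbind(bs[nrow(bs), , drop = FALSE], ref_end_side = "end"))
  }))
  cand <- list()
  for (p in unique(term$partner_scaffold)) {
    tb <- term[term$partner_scaffold == p, , drop = FALSE]
    if (nrow(tb) < 2L) next
    tb <- tb[order(tb$partner_start), , drop = FALSE]
    pb <- blocks[blocks$partner_scaffold == p, , drop = FALSE]
    for (u in seq_len(nrow(tb) - 1L)) {
      b1 <- tb[u, ]; b2 <- tb[u + 1L, ]
      if (b1$ref_scaffold == b2$ref_scaffold) next
      ## adjacency on the partner scaffold: no other block in between
      between <- pb$partner_start >= b1$partner_end &
        pb$partner_end <= b2$partner_start &
        !(pb$block_id %in% c(b1$block_id, b2$block_id))
      if (any(between)) next
      cand[[length(cand) + 1L]] <- data.frame(
        ref_a = b1$ref_scaffold, end_a = b1$ref_end_side,
        ref_b = b2$ref_scaffold, end_b = b2$ref_end_side,
        partner_scaffold = p,
        support = b1$n_markers + b2$n_markers,
        conflict = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  links <- do.call(rbind, cand)
  links <- links[order(-links$support), , drop = FALSE]
  taken <- character()
  keep <- logical(nrow(links))
  for (i in seq_len(nrow(links))) {
    ka <- paste(links$ref_a[i], links$end_a[i])
    kb <- paste(links$ref_b[i], links$end_b[i])
    if (ka %in% taken || kb %in% taken) {
      links$conflict[keep][match(TRUE, (paste(links$ref_a[keep], links$end_a[keep]) == ka |
                                        paste(links$ref_b[keep], links$end_b[keep]) == kb))] <- TRUE
      next
    }
    taken <- c(taken, ka, kb)
    keep[i] <- TRUE
  }
  out <- links[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propose chromosome placements for unplaced reference scaffolds
#'
#' An unplaced reference scaffold receives a putative chromosome when one of
#' its blocks has at least `min_placement_support` consecutive markers on a
#' partner scaffold that also carries markers of chromosome-placed reference
#' scaffolds, and the unplaced block's partner range falls into a gap between
#' those markers or beyond their ends (never on top of one). The input
#' chromosome map is not modified; placements are returned as annotations.
#'
#' @param blocks block data.frame from [build_blocks()].
#' @param markers marker data.frame from [build_blocks()] (the `markers`
#'   element, carrying block assignments and chromosome annotations).
#' @param params [synteny_params()].
#' @return `blocks` with an added `placed_chrom` column (NA where no placement
#'   was made).
#' @export
place_unplaced <- function(blocks, markers, params = synteny_params()) {
  blocks$placed_chrom <- NA_character_
  if (nrow(blocks) == 0L) return(blocks)
  unpl <- which(blocks$ref_chrom == "unplaced" &
                blocks$n_markers >= params$min_placement_support)
  anchor_markers <- markers[markers$status == "used" &
                            markers$ref_chrom != "unplaced", , drop = FALSE]
  for (i in unpl) {
    am <- anchor_markers[
      anchor_markers$scaffold_b == blocks$partner_scaffold[i], , drop = FALSE]
    if (nrow(am) == 0L) next
    chroms <- unique(am$ref_chrom)
    if (length(chroms) != 1L) next   # ambiguous partner context
    on_top <- am$start_b < blocks$partner_end[i] &
      am$end_b > blocks$partner_start[i]
    if (any(on_top)) next            # must fall into a gap or at an end
    blocks$placed_chrom[i] <- chroms
  }
  blocks
}

#' Summarize a synteny map
#'
#' @param blocks block data.frame from [build_blocks()].
#' @param events event data.frame from [classify_rearrangements()].
#' @param assembly_ref,assembly_partner the two assemblies (for coverage
#'   denominators); optional.
#' @param params [synteny_params()] (supplies the large-block threshold).
#' @return list of class `SyntenySummary`: block count, reference/partner
#'   block-length statistics (mean, median, min, max, total), number of
#'   reference scaffolds covered, coverage fraction of each assembly, number
#'   of large blocks, and intra/inter event counts.
#' @export
summarize_synteny <- function(blocks, events,
                              assembly_ref = NULL, assembly_partner = NULL,
                              params = synteny_params()) {
  span_ref <- blocks$ref_end - blocks$ref_start
  span_partner <- blocks$partner_end - blocks$partner_start
  len_stats <- function(x) {
    if (!length(x)) return(list(mean = NA_real_, median = NA_real_,
                                min = NA_real_, max = NA_real_, total = 0))
    list(mean = mean(x), median = median(x), min = min(x), max = max(x),
         total = sum(as.numeric(x)))
  }
  cov <- function(total, asm) {
    if (is.null(asm)) return(NA_real_)
    total / sum(as.numeric(nchar(asm$seq)))
  }
  structure(list(
    n_blocks = nrow(blocks),
    ref = len_stats(span_ref),
    partner = len_stats(span_partner),
    n_ref_scaffolds_covered = length(unique(blocks$ref_scaffold)),
    coverage_ref = cov(sum(as.numeric(span_ref)), assembly_ref),
    coverage_partner = cov(sum(as.numeric(span_partner)), assembly_partner),
    n_large_blocks = sum(span_ref > params$large_block_threshold),
    n_intra = sum(events$type == "intra"),
    n_inter = sum(events$type == "inter")
  ), class = "SyntenySummary")
}

#' @export
print.SyntenySummary <- function(x, ...) {
  cat(sprintf("Synteny summary: %d blocks on %d reference scaffolds\n",
              x$n_blocks, x$n_ref_scaffolds_covered))
  if (x$n_blocks > 0L)
    cat(sprintf("  block length (ref): mean %.2f Mb, median %.2f Mb, total %.1f Mb\n",
                x$ref$mean / 1e6, x$ref$median / 1e6, x$ref$total / 1e6))
  cat(sprintf("  coverage: reference %s, partner %s; %d blocks > threshold\n",
              ifelse(is.na(x$coverage_ref), "NA", sprintf("%.1f%%", 100 * x$coverage_ref)),
              ifelse(is.na(x$coverage_partner), "NA", sprintf("%.1f%%", 100 * x$coverage_partner)),
              x$n_large_blocks))
  cat(sprintf("  rearrangements: %d intra-, %d inter-chromosomal\n",
              x$n_intra, x$n_inter))
  invisible(x)
}
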