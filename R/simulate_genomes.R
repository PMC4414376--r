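## Synthetic assembly pairs with ground truth. Two assemblies descend from
## one simulated ancestor that carries implanted SSR loci; one of them (role
## B) additionally receives a known history of inversions and
## inter-chromosomal translocations. Both branches then accumulate
## independent point mutations and small indels outside the SSR intervals,
## and can optionally be fragmented with N gaps. Truth tables record the
## lifted coordinates of every implanted locus, the homologous pairs, and
## the rearrangement breakpoints in reference coordinates.

.RAW_BASES <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T
.RAW_N <- as.raw(78L)

#' Simulation parameters for an assembly pair
#'
#' Defaults describe the standard study condition used throughout the test
#' suite: a 10 Mb, 5-chromosome genome carrying 400 SSR loci (40 per Mb),
#' pairwise flank divergence of 0.5%, and a rearrangement history of 6
#' inversions and 4 translocations, each spanning at least `markers_per_event`
#' markers. Fragmentation defaults to off.
#'
#' @param genome_size total ancestor length in bp.
#' @param n_chromosomes number of ancestor chromosomes (equal sizes).
#' @param gc GC content of the background sequence.
#' @param ssr_per_mb implanted SSR density (loci per Mb).
#' @param motif_mix sampling weights for motif lengths 1..6.
#' @param ssr_min_units implanted minimum units per motif length (matched to
#'   the detection minima so implanted loci are detectable).
#' @param ssr_extra_units mean of the Poisson excess over the minimum.
#' @param ssr_spacing minimum distance between implanted loci (bp).
#' @param mu pairwise flank divergence: each branch receives point mutations
#'   at rate `mu/2` per base, so A-vs-B mismatch is about `mu`.
#' @param indel_rate pairwise small-indel rate (1-3 bp), split between the
#'   branches like `mu`.
#' @param n_inversions,n_translocations rearrangement history applied to the
#'   role-B genome.
#' @param markers_per_event implanted markers contained in each rearranged
#'   segment.
#' @param event_buffer_markers markers kept clear between/around segments.
#' @param gaps_per_mb N-gap runs inserted per Mb in each derived assembly.
#' @param gap_len length of each inserted N run.
#' @param breaks_per_mb scaffold fragmentation breakpoints per Mb.
#' @param unplaced_frac fraction of derived scaffolds left out of the
#'   chromosome map ("unplaced").
#' @param seed RNG seed used by [simulate_assembly_pair()].
#' @return list of class `sim_params`.
#' @export
sim_params <- function(genome_size = 10e6,
                       n_chromosomes = 5L,
                       gc = 0.38,
                       ssr_per_mb = 40,
                       motif_mix = c(0.05, 0.40, 0.25, 0.15, 0.10, 0.05),
                       ssr_min_units = c(12L, 6L, 5L, 5L, 5L, 5L),
                       ssr_extra_units = 2,
                       ssr_spacing = 500L,
                       mu = 0.005,
                       indel_rate = 2e-4,
                       n_inversions = 6L,
                       n_translocations = 4L,
                       markers_per_event = 6L,
                       event_buffer_markers = 3L,
                       gaps_per_mb = 0,
                       gap_len = 100L,
                       breaks_per_mb = 0,
                       unplaced_frac = 0,
                       seed = 1L) {
  stopifnot(mu >= 0, mu <= 1, indel_rate >= 0, gc > 0, gc < 1,
            genome_size >= n_chromosomes * 1e4)
  structure(as.list(environment()), class = "sim_params")
}

gen_background <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  .RAW_BASES[sample.int(4L, n, replace = TRUE, prob = p)]
}

random_irreducible_motif <- function(k) {
  repeat {
    m <- rawToChar(.RAW_BASES[sample.int(4L, k, replace = TRUE)])
    if (!is_reducible_motif(m)) return(m)
  }
}

#' Simulate an ancestor genome with implanted SSR loci
#'
#' Background sequence is iid at the stated GC; perfect SSR runs are
#' implanted at uniform-random positions with at least `ssr_spacing` bp
#' between loci. The bases immediately flanking each implanted run are forced
#' non-extending, so the implanted unit count is exactly what a perfect-repeat
#' scan recovers.
#'
#' @param params [sim_params()].
#' @return list with `chroms` (named character vector, chr1..chrK) and `loci`
#'   (data.frame: `anc_id`, `chrom`, `start`, `end`, `motif`, `motif_len`,
#'   `n_units`).
#' @export
simulate_ancestor <- function(params = sim_params()) {
  k_chrom <- params$n_chromosomes
  chrom_len <- rep(params$genome_size %/% k_chrom, k_chrom)
  chrom_len[k_chrom] <- chrom_len[k_chrom] + params$genome_size %% k_chrom
  chrom_names <- paste0("chr", seq_len(k_chrom))
  n_loci_total <- round(params$ssr_per_mb * params$genome_size / 1e6)
  n_per <- floor(n_loci_total * chrom_len / sum(chrom_len))
  n_per[1L] <- n_per[1L] + n_loci_total - sum(n_per)

  margin <- 300L
  min_sep <- params$ssr_spacing
  chroms <- character(k_chrom)
  loci <- vector("list", k_chrom)
  next_id <- 1L
  for (ci in seq_len(k_chrom)) {
    L <- chrom_len[ci]
    n <- n_per[ci]
    avail <- L - 2L * margin - n * min_sep
    if (avail <= n)
      abort("simulate_ancestor: SSR density too high for %d bp spacing", min_sep)
    u <- sort(sample.int(avail, n))
    pos <- margin + u + (seq_len(n) - 1L) * min_sep     # 0-based starts
    r <- gen_background(L, params$gc)
    df <- data.frame(anc_id = seq.int(next_id, length.out = n),
                     chrom = chrom_names[ci], start = pos, end = pos,
                     motif = "", motif_len = 0L, n_units = 0L,
                     stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      k <- sample.int(6L, 1L, prob = params$motif_mix)
      motif <- random_irreducible_motif(k)
      units <- params$ssr_min_units[k] + rpois(1L, params$ssr_extra_units)
      len <- k * units
      mraw <- charToRaw(motif)
      st <- pos[i]                                      # 0-based
      r[(st + 1L):(st + len)] <- rep(mraw, units)
      ## non-extending guards (keep 0-based index st-1 and st+len clear)
      r[st] <- sample(.RAW_BASES[.RAW_BASES != mraw[k]], 1L)
      r[st + len + 1L] <- sample(.RAW_BASES[.RAW_BASES != mraw[1L]], 1L)
      df$end[i] <- st + len
      df$motif[i] <- canonical_motif(motif)
      df$motif_len[i] <- k
      df$n_units[i] <- units
    }
    chroms[ci] <- rawToChar(r)
    loci[[ci]] <- df
    next_id <- next_id + n
  }
  names(chroms) <- chrom_names
  list(chroms = chroms, loci = do.call(rbind, loci))
}

## Pick rearranged segments as runs of consecutive implanted loci; segment
## boundaries are midpoints between the run and its outside neighbours, so no
## locus straddles a breakpoint and every segment carries its markers.
generate_rearrangements <- function(ancestor, params) {
  loci <- ancestor$loci
  m <- params$markers_per_event
  buf <- params$event_buffer_markers
  used <- logical(nrow(loci))
  events <- list()
  n_ev <- params$n_inversions + params$n_translocations
  types <- sample(c(rep("inversion", params$n_inversions),
                    rep("translocation", params$n_translocations)))
  chrom_ids <- names(ancestor$chroms)
  for (ev in seq_len(n_ev)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      chrom <- sample(chrom_ids, 1L)
      idx <- which(loci$chrom == chrom)
      if (length(idx) < m + 2L * (buf + 1L)) next
      s0 <- sample.int(length(idx) - m - 2L * buf, 1L) + buf   # run start offset
      run <- idx[s0:(s0 + m - 1L)]
      guard <- idx[max(1L, s0 - buf):min(length(idx), s0 + m - 1L + buf)]
      if (any(used[guard])) next
      prev <- idx[s0 - 1L]
      nxt <- idx[s0 + m]
      seg_start <- (loci$end[prev] + loci$start[run[1L]]) %/% 2L
      seg_end <- (loci$end[run[m]] + loci$start[nxt]) %/% 2L
      dest_chrom <- NA_character_; dest_pos <- NA_integer_
      if (types[ev] == "translocation") {
        ok_dest <- FALSE
        for (dtry in seq_len(200L)) {
          dc <- sample(setdiff(chrom_ids, chrom), 1L)
          didx <- which(loci$chrom == dc)
          if (length(didx) < 2L * buf + 2L) next
          di <- sample.int(length(didx) - 1L - 2L * buf, 1L) + buf
          d1 <- didx[di]; d2 <- didx[di + 1L]
          dguard <- didx[max(1L, di - buf):min(length(didx), di + 1L + buf)]
          if (any(used[dguard])) next
          dest_chrom <- dc
          dest_pos <- (loci$end[d1] + loci$start[d2]) %/% 2L
          used[dguard] <- TRUE
          ok_dest <- TRUE
          break
        }
        if (!ok_dest) next
      }
      used[guard] <- TRUE
      events[[ev]] <- data.frame(
        event_id = ev, type = types[ev], chrom = chrom,
        start = seg_start, end = seg_end,
        dest_chrom = dest_chrom, dest_pos = dest_pos,
        n_markers = m, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      abort("generate_rearrangements: could not place event %d; genome too crowded", ev)
  }
  do.call(rbind, events)
}

## Segment table of a derived genome: one row per ancestor interval in output
## order, with output scaffold and strand. Identity when events is NULL.
build_segments <- function(chroms, events = NULL) {
  lens <- nchar(chroms)
  segs <- lapply(names(chroms), function(cn) {
    cuts <- c(0L, lens[[cn]])
    if (!is.null(events)) {
      onc <- events[events$chrom == cn, , drop = FALSE]
      cuts <- c(cuts, onc$start, onc$end,
                events$dest_pos[!is.na(events$dest_chrom) &
                                events$dest_chrom == cn])
    }
    cuts <- sort(unique(cuts))
    data.frame(anc_chrom = cn,
               anc_start = cuts[-length(cuts)], anc_end = cuts[-1L],
               strand = "+", out_chrom = cn, stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  if (!is.null(events)) {
    for (ei in seq_len(nrow(events))) {
      e <- events[ei, ]
      hit <- which(segs$anc_chrom == e$chrom & segs$anc_start == e$start &
                   segs$anc_end == e$end)
      stopifnot(length(hit) == 1L)
      if (e$type == "inversion") {
        segs$strand[hit] <- "-"
      } else {
        piece <- segs[hit, , drop = FALSE]
        piece$out_chrom <- e$dest_chrom
        segs <- segs[-hit, , drop = FALSE]
        at <- which(segs$out_chrom == e$dest_chrom &
                    segs$anc_start == e$dest_pos &
                    segs$anc_chrom == e$dest_chrom)
        stopifnot(length(at) == 1L)
        segs <- rbind(segs[seq_len(at - 1L), , drop = FALSE], piece,
                      segs[at:nrow(segs), , drop = FALSE])
      }
    }
  }
  ## output coordinates per derived chromosome
  segs <- do.call(rbind, lapply(split(segs, segs$out_chrom), function(sc) {
    sc$out_start <- cumsum(c(0L, head(sc$anc_end - sc$anc_start, -1L)))
    sc
  }))
  rownames(segs) <- NULL
  segs
}

## render derived chromosome sequences from a segment table
render_segments <- function(chroms, segs) {
  out <- lapply(split(segs, segs$out_chrom), function(sc) {
    pieces <- vapply(seq_len(nrow(sc)), function(i) {
      s <- substr(chroms[[sc$anc_chrom[i]]], sc$anc_start[i] + 1L, sc$anc_end[i])
      if (sc$strand[i] == "-") revcomp(s) else s
    }, "")
    paste(pieces, collapse = "")
  })
  unlist(out)
}

## lift 0-based ancestor intervals through a segment table (pre-indel coords)
lift_intervals <- function(df, segs) {
  out_chrom <- character(nrow(df))
  out_start <- integer(nrow(df)); out_end <- integer(nrow(df))
  strand <- character(nrow(df))
  for (cn in unique(df$chrom)) {
    rows <- which(df$chrom == cn)
    sc <- segs[segs$anc_chrom == cn, , drop = FALSE]
    sc <- sc[order(sc$anc_start), , drop = FALSE]
    seg_i <- findInterval(df$start[rows], sc$anc_start)
    for (q in seq_along(rows)) {
      i <- rows[q]; sr <- sc[seg_i[q], ]
      if (df$end[i] > sr$anc_end)
        abort("lift_intervals: interval crosses a segment boundary")
      if (sr$strand == "+") {
        out_start[i] <- sr$out_start + (df$start[i] - sr$anc_start)
        out_end[i] <- sr$out_start + (df$end[i] - sr$anc_start)
      } else {
        out_start[i] <- sr$out_start + (sr$anc_end - df$end[i])
        out_end[i] <- sr$out_start + (sr$anc_end - df$start[i])
      }
      out_chrom[i] <- sr$out_chrom
      strand[i] <- sr$strand
    }
  }
  data.frame(scaffold = out_chrom, start = out_start, end = out_end,
             strand = strand, stringsAsFactors = FALSE)
}

## point mutations outside protected intervals; raw in, raw out
apply_mutations <- function(r, rate, protect_start, protect_end) {
  n <- length(r)
  n_mut <- rbinom(1L, n, rate)
  if (n_mut == 0L) return(r)
  prot <- logical(n)
  if (length(protect_start))
    for (i in seq_along(protect_start))
      prot[(protect_start[i] + 1L):protect_end[i]] <- TRUE
  cand <- which(!prot)
  pos <- cand[sample.int(length(cand), min(n_mut, length(cand)))]
  cur <- match(r[pos], .RAW_BASES)
  shift <- sample.int(3L, length(pos), replace = TRUE)
  r[pos] <- .RAW_BASES[((cur - 1L + shift) %% 4L) + 1L]
  r
}

## indel/gap edits: events (pos = 0-based original coordinate, delta, fill).
## Returns list(seq, shifts) where shifts has thresholds in original coords.
apply_indels <- function(r, edits) {
  if (is.null(edits) || nrow(edits) == 0L)
    return(list(seq = r, shifts = data.frame(t = integer(), delta = integer())))
  edits <- edits[order(edits$pos), , drop = FALSE]
  n <- length(r)
  pieces <- list()
  cursor <- 0L   # 0-based, next original base to copy
  t_thr <- integer(nrow(edits)); deltas <- integer(nrow(edits))
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]; d <- edits$delta[i]
    if (p > cursor) pieces[[length(pieces) + 1L]] <- r[(cursor + 1L):p]
    if (d > 0L) {            # insertion before original position p
      pieces[[length(pieces) + 1L]] <- edits$fill[[i]]
      cursor <- p
      t_thr[i] <- p
    } else {                 # deletion of [p, p - d)
      cursor <- p - d
      t_thr[i] <- p - d
    }
    deltas[i] <- d
  }
  if (cursor < n) pieces[[length(pieces) + 1L]] <- r[(cursor + 1L):n]
  list(seq = do.call(c, pieces),
       shifts = data.frame(t = t_thr, delta = deltas))
}

## total shift for original 0-based positions
shift_at <- function(pos, shifts) {
  if (nrow(shifts) == 0L) return(rep(0L, length(pos)))
  cs <- cumsum(shifts$delta)
  i <- findInterval(pos, shifts$t)
  ifelse(i == 0L, 0L, cs[pmax(i, 1L)])
}

## invert the shift map: final coordinate -> original coordinate
unshift_at <- function(pos, shifts) {
  if (nrow(shifts) == 0L) return(pos)
  cs <- cumsum(shifts$delta)
  thr_final <- shifts$t + cs           # final coordinate of each threshold
  i <- findInterval(pos, thr_final)
  ifelse(i == 0L, pos, pos - cs[pmax(i, 1L)])
}

#' Derive one assembly from a simulated ancestor
#'
#' Role "B" receives the rearrangement history; both roles then receive
#' independent point mutations (rate `mu/2`) and small indels outside the
#' implanted SSR intervals, optional N-gap insertion, and optional scaffold
#' fragmentation. Truth coordinates of all implanted loci are lifted along.
#'
#' @param ancestor output of [simulate_ancestor()].
#' @param params [sim_params()].
#' @param role "A" (reference, collinear with the ancestor) or "B" (carries
#'   the rearrangements).
#' @param events rearrangement table (required for role "B" when the history
#'   is non-empty); see [generate_rearrangements()].
#' @return list: `assembly` ([assembly()]), `chrom_map`, `loci` (truth loci in
#'   derived coordinates, with `strand`), and internal lift structures
#'   (`segments`, `shifts`, `frag`) used by [unlift_position()].
#' @export
derive_assembly <- function(ancestor, params, role = c("A", "B"),
                            events = NULL) {
  role <- match.arg(role)
  if (role == "A") events <- NULL
  if (!is.null(events) && nrow(events) == 0L) events <- NULL
  segs <- build_segments(ancestor$chroms, events)
  seqs <- render_segments(ancestor$chroms, segs)
  lifted <- lift_intervals(ancestor$loci[, c("chrom", "start", "end")], segs)
  names(lifted) <- c("scaffold", "d_start", "d_end", "strand")
  loci <- cbind(ancestor$loci, lifted)
  ## per-scaffold edits
  shifts <- list()
  out_seqs <- list()
  for (scaf in names(seqs)) {
    r <- charToRaw(seqs[[scaf]])
    sel <- loci$scaffold == scaf
    ps <- loci$d_start[sel]; pe <- loci$d_end[sel]
    r <- apply_mutations(r, params$mu / 2, ps, pe)
    ## small indels + N gaps, all outside loci +- margin
    n <- length(r)
    margin <- 6L
    prot <- logical(n)
    if (length(ps))
      for (i in seq_along(ps))
        prot[max(1L, ps[i] - margin + 1L):min(n, pe[i] + margin)] <- TRUE
    prot[max(1L, n - 10L):n] <- TRUE
    cand <- which(!prot)
    n_indel <- rbinom(1L, n, params$indel_rate / 2)
    n_gap <- rpois(1L, params$gaps_per_mb * n / 1e6)
    edits <- NULL
    if (n_indel + n_gap > 0L && length(cand) > n_indel + n_gap) {
      pos <- sort(cand[sample.int(length(cand), n_indel + n_gap)]) - 1L
      is_gap <- rep(FALSE, length(pos))
      if (n_gap > 0L) is_gap[sample.int(length(pos), n_gap)] <- TRUE
      rows <- lapply(seq_along(pos), function(i) {
        if (is_gap[i]) {
          list(pos = pos[i], delta = params$gap_len,
               fill = list(rep(.RAW_N, params$gap_len)))
        } else {
          d <- sample.int(3L, 1L)
          if (runif(1L) < 0.5)
            list(pos = pos[i], delta = d,
                 fill = list(gen_background(d, params$gc)))
          else
            list(pos = pos[i], delta = -d, fill = list(raw()))
        }
      })
      edits <- data.frame(pos = vapply(rows, `[[`, 0, "pos"),
                          delta = vapply(rows, `[[`, 0, "delta"))
      edits$fill <- lapply(rows, function(x) x$fill[[1L]])
      ## drop overlapping deletions
      keep <- c(TRUE, diff(edits$pos) > 4L)
      edits <- edits[keep, , drop = FALSE]
    }
    res <- apply_indels(r, edits)
    out_seqs[[scaf]] <- rawToChar(res$seq)
    shifts[[scaf]] <- res$shifts
  }
  ## shift truth loci
  for (scaf in names(out_seqs)) {
    sel <- which(loci$scaffold == scaf)
    if (!length(sel)) next
    sh <- shift_at(loci$d_start[sel], shifts[[scaf]])
    loci$d_start[sel] <- loci$d_start[sel] + sh
    loci$d_end[sel] <- loci$d_end[sel] + sh
  }
  ## fragmentation
  frag <- NULL
  if (params$breaks_per_mb > 0) {
    frag_rows <- list()
    new_seqs <- list()
    for (scaf in names(out_seqs)) {
      s <- out_seqs[[scaf]]
      n <- nchar(s)
      nb <- rpois(1L, params$breaks_per_mb * n / 1e6)
      sel <- which(loci$scaffold == scaf)
      prot <- logical(n)
      if (length(sel))
        for (i in sel)
          prot[max(1L, loci$d_start[i] - 250L):min(n, loci$d_end[i] + 250L)] <- TRUE
      cand <- which(!prot)
      cuts <- sort(unique(c(0L, if (nb > 0L && length(cand) > nb)
        cand[sample.int(length(cand), nb)] - 1L else integer(), n)))
      for (pi in seq_len(length(cuts) - 1L)) {
        piece <- sprintf("%s_p%d", scaf, pi)
        frag_rows[[length(frag_rows) + 1L]] <- data.frame(
          scaffold = scaf, piece = piece,
          start = cuts[pi], end = cuts[pi + 1L], stringsAsFactors = FALSE)
        new_seqs[[piece]] <- substr(s, cuts[pi] + 1L, cuts[pi + 1L])
      }
    }
    frag <- do.call(rbind, frag_rows)
    out_seqs <- new_seqs
    ## remap truth loci into pieces
    for (i in seq_len(nrow(loci))) {
      rows <- frag[frag$scaffold == loci$scaffold[i] &
                   frag$start <= loci$d_start[i] &
                   frag$end >= loci$d_end[i], , drop = FALSE]
      if (nrow(rows) == 1L) {
        loci$d_start[i] <- loci$d_start[i] - rows$start
        loci$d_end[i] <- loci$d_end[i] - rows$start
        loci$scaffold[i] <- rows$piece
      }
    }
  }
  scaffold_names <- paste0(role, "_", names(out_seqs))
  lookup <- setNames(scaffold_names, names(out_seqs))
  loci$scaffold <- unname(lookup[loci$scaffold])
  names(out_seqs) <- scaffold_names
  asm <- assembly(unlist(out_seqs), name = paste0("sim_", role))
  raw_names <- sub("^[AB]_", "", scaffold_names)
  base_chrom <- if (is.null(frag)) raw_names else
    frag$scaffold[match(raw_names, frag$piece)]
  chrom_map <- setNames(base_chrom, scaffold_names)
  chrom_map <- chrom_map[!is.na(chrom_map)]
  if (params$unplaced_frac > 0 && length(chrom_map) > 1L) {
    drop_n <- floor(params$unplaced_frac * length(chrom_map))
    if (drop_n > 0L)
      chrom_map <- chrom_map[-sample.int(length(chrom_map), drop_n)]
  }
  truth_loci <- data.frame(anc_id = loci$anc_id, scaffold = loci$scaffold,
                           start = loci$d_start, end = loci$d_end,
                           motif = loci$motif, motif_len = loci$motif_len,
                           n_units = loci$n_units, strand = loci$strand,
                           stringsAsFactors = FALSE)
  list(assembly = asm, chrom_map = chrom_map, loci = truth_loci,
       segments = segs, shifts = shifts, frag = frag, role = role)
}

#' Map a derived-assembly position back to ancestor coordinates
#'
#' Inverts fragmentation, indel shifts, and the rearrangement segment map.
#'
#' @param derived a list from [derive_assembly()].
#' @param scaffold,pos derived scaffold id(s) and 0-based position(s).
#' @return data.frame with `anc_chrom` and `anc_pos`.
#' @export
unlift_position <- function(derived, scaffold, pos) {
  scaffold <- sub(paste0("^", derived$role, "_"), "", scaffold)
  anc_chrom <- character(length(pos)); anc_pos <- integer(length(pos))
  for (i in seq_along(pos)) {
    scaf <- scaffold[i]; p <- pos[i]
    if (!is.null(derived$frag)) {
      row <- derived$frag[derived$frag$piece == scaf, , drop = FALSE]
      p <- p + row$start[1L]
      scaf <- row$scaffold[1L]
    }
    p <- unshift_at(p, derived$shifts[[scaf]])
    sc <- derived$segments[derived$segments$out_chrom == scaf, , drop = FALSE]
    sc <- sc[order(sc$out_start), , drop = FALSE]
    j <- findInterval(p, sc$out_start)
    j <- max(1L, min(j, nrow(sc)))
    if (sc$strand[j] == "+") {
      anc_pos[i] <- sc$anc_start[j] + (p - sc$out_start[j])
    } else {
      anc_pos[i] <- sc$anc_end[j] - 1L - (p - sc$out_start[j])
    }
    anc_chrom[i] <- sc$anc_chrom[j]
  }
  data.frame(anc_chrom = anc_chrom, anc_pos = anc_pos,
             stringsAsFactors = FALSE)
}

#' Simulate a homologous assembly pair with known truth
#'
#' Builds one ancestor, derives the reference assembly A (collinear) and the
#' rearranged assembly B, and assembles the truth tables: per-assembly lifted
#' locus coordinates, the homologous pair list, and the rearrangement events
#' with their reference-coordinate breakpoints.
#'
#' @param params [sim_params()].
#' @return list of class `ssr_simulation`: `a`, `b` (from
#'   [derive_assembly()]), `ancestor`, `events` (with reference breakpoint
#'   columns `ref_scaffold`, `ref_start`, `ref_end`), and `pairs` (truth
#'   pairs: ancestor locus id plus per-assembly scaffold/interval).
#' @export
simulate_assembly_pair <- function(params = sim_params()) {
  set.seed(params$seed)
  ancestor <- simulate_ancestor(params)
  events <- if (params$n_inversions + params$n_translocations > 0L)
    generate_rearrangements(ancestor, params) else NULL
  a <- derive_assembly(ancestor, params, "A")
  b <- derive_assembly(ancestor, params, "B", events = events)
  pairs <- merge(a$loci, b$loci, by = "anc_id", suffixes = c("_a", "_b"))
  ## reference-coordinate breakpoints of the true events (A is collinear with
  ## the ancestor up to indel shifts and fragmentation)
  ev <- NULL
  if (!is.null(events)) {
    ev <- events
    ev$ref_scaffold <- NA_character_
    ev$ref_start <- NA_integer_
    ev$ref_end <- NA_integer_
    for (i in seq_len(nrow(ev))) {
      sh <- a$shifts[[ev$chrom[i]]]
      rs <- ev$start[i] + shift_at(ev$start[i], sh)
      re <- ev$end[i] + shift_at(ev$end[i], sh)
      scaf <- ev$chrom[i]
      if (!is.null(a$frag)) {
        row <- a$frag[a$frag$scaffold == scaf & a$frag$start <= rs &
                      a$frag$end >= re, , drop = FALSE]
        if (nrow(row) == 1L) {
          rs <- rs - row$start; re <- re - row$start
          scaf <- row$piece
        }
      }
      ev$ref_scaffold[i] <- paste0("A_", scaf)
      ev$ref_start[i] <- rs
      ev$ref_end[i] <- re
    }
  }
  structure(list(a = a, b = b, ancestor = ancestor, events = ev,
                 pairs = pairs, params = params),
            class = "ssr_simulation")
}
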