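# Hand-built marker tables: markers on one reference scaffold with explicit
# partner coordinates; pair/track columns as produced by the real pipeline.
mk_markers <- function(ref = "r1", partner, pos_b, orient = "+",
                       pos_a = seq_along(pos_b) * 1000L) {
  data.frame(locus_a = paste0(ref, ":", pos_a), scaffold_a = ref,
             start_a = pos_a, end_a = pos_a + 20L,
             locus_b = paste0(partner, ":", pos_b), scaffold_b = partner,
             start_b = pos_b, end_b = pos_b + 20L,
             motif = "AC", identity = 1, aligned_fraction = 1,
             orientation = orient, stringsAsFactors = FALSE)
}

test_that("tracks are sorted and annotated with chromosomes", {
  m <- mk_markers(partner = "p1", pos_b = c(300L, 100L, 200L))
  m <- m[c(2, 3, 1), ]
  tr <- build_tracks(m, c(r1 = "LG1"), character())
  expect_equal(tr$start_a, sort(m$start_a))
  expect_equal(unique(tr$ref_chrom), "LG1")
  expect_equal(unique(tr$partner_chrom), "unplaced")
  expect_equal(nrow(build_tracks(m[0, ], character(), character())), 0L)
})

test_that("concordant markers chain into one block", {
  tr <- build_tracks(mk_markers(partner = "p1", pos_b = (1:10) * 500L),
                     character(), character())
  res <- build_blocks(tr)
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$n_markers, 10L)
  expect_equal(res$blocks$orientation, "+")
  expect_true(all(res$markers$status == "used"))
})

test_that("a single discordant locus is ignored without breaking the block", {
  m <- mk_markers(partner = "p1", pos_b = (1:10) * 500L)
  m$scaffold_b[5] <- "px"; m$locus_b[5] <- "px:1"
  res <- build_blocks(build_tracks(m, character(), character()))
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$n_markers, 9L)
  expect_equal(sum(res$markers$status == "ignored"), 1L)
})

test_that("an inverted run splits into three blocks with the right bounds", {
  pos_b <- c(1:3 * 500L, rev(4:7) * 500L + 10000L, 8:10 * 500L + 20000L)
  ori <- c(rep("+", 3), rep("-", 4), rep("+", 3))
  m <- mk_markers(partner = "p1", pos_b = pos_b, orient = ori)
  res <- build_blocks(build_tracks(m, character(), character()))
  expect_equal(res$blocks$orientation, c("+", "-", "+"))
  expect_equal(res$blocks$n_markers, c(3L, 4L, 3L))
  expect_equal(res$blocks$ref_start, c(1000L, 4000L, 8000L))
  # partner coordinates are monotone within each block
  for (bid in res$blocks$block_id) {
    mem <- res$markers[which(res$markers$block_id == bid), ]
    d <- diff(mem$start_b)
    expect_true(all(d > 0) || all(d < 0))
  }
})

test_that("blocks with fewer than two markers are discarded", {
  # two consecutive discordant loci pointing at two different scaffolds break
  # the chain but can seed only one-marker blocks, which are discarded
  m <- mk_markers(partner = "p1", pos_b = c(1:4 * 500L, 1L, 1L, 7:10 * 500L))
  m$scaffold_b[5:6] <- c("px", "py")
  m$locus_b[5:6] <- c("px:1", "py:1")
  res <- build_blocks(build_tracks(m, character(), character()))
  expect_equal(nrow(res$blocks), 2L)
  expect_equal(res$blocks$n_markers, c(4L, 4L))
  expect_equal(sum(res$markers$status == "ignored"), 2L)
})

test_that("rearrangement classification counts events, not boundaries", {
  # inversion: +,-,+ on one partner chromosome -> one intra event
  pos_b <- c(1:3 * 500L, rev(4:7) * 500L, 8:10 * 500L)
  ori <- c(rep("+", 3), rep("-", 4), rep("+", 3))
  m <- mk_markers(partner = "p1", pos_b = pos_b, orient = ori)
  res <- build_blocks(build_tracks(m, c(r1 = "LG1"), c(p1 = "c1")))
  ev <- classify_rearrangements(res$blocks)
  expect_equal(ev$type, "intra")
  expect_equal(ev$bp1_start, res$blocks$ref_end[1])
  expect_equal(ev$bp1_end, res$blocks$ref_start[2])

  # translocated insertion: chromosome pattern c1,c2,c1 -> one inter event
  m2 <- rbind(mk_markers(partner = "p1", pos_b = 1:4 * 500L,
                         pos_a = 1:4 * 1000L),
              mk_markers(partner = "p2", pos_b = 1:3 * 500L,
                         pos_a = 5:7 * 1000L),
              mk_markers(partner = "p1", pos_b = 5:8 * 500L,
                         pos_a = 8:11 * 1000L))
  res2 <- build_blocks(build_tracks(m2, c(r1 = "LG1"),
                                    c(p1 = "c1", p2 = "c2")))
  ev2 <- classify_rearrangements(res2$blocks)
  expect_equal(ev2$type, "inter")
  expect_equal(ev2$partner_chrom, "c2")

  # collinear genomes -> no events
  res3 <- build_blocks(build_tracks(
    mk_markers(partner = "p1", pos_b = 1:10 * 500L),
    c(r1 = "LG1"), c(p1 = "c1")))
  expect_equal(nrow(classify_rearrangements(res3$blocks)), 0L)

  # partner scaffold change within one chromosome is an assembly break
  m4 <- rbind(mk_markers(partner = "p1", pos_b = 1:5 * 500L,
                         pos_a = 1:5 * 1000L),
              mk_markers(partner = "p2", pos_b = 1:5 * 500L,
                         pos_a = 6:10 * 1000L))
  res4 <- build_blocks(build_tracks(m4, c(r1 = "LG1"),
                                    c(p1 = "c1", p2 = "c1")))
  expect_equal(nrow(classify_rearrangements(res4$blocks)), 0L)
})

test_that("scaffold linking requires adjacency on the bridging scaffold", {
  # partner p1 spans the end of refA and the start of refB contiguously
  m <- rbind(mk_markers(ref = "refA", partner = "p1", pos_b = 1:5 * 500L,
                        pos_a = 1:5 * 1000L),
             mk_markers(ref = "refB", partner = "p1",
                        pos_b = 6:10 * 500L, pos_a = 1:5 * 1000L))
  res <- build_blocks(build_tracks(m, character(), character()))
  links <- link_scaffolds(res$blocks)
  expect_equal(nrow(links), 1L)
  expect_setequal(c(links$ref_a, links$ref_b), c("refA", "refB"))

  # no bridging partner scaffold -> no links
  m2 <- rbind(mk_markers(ref = "refA", partner = "p1", pos_b = 1:5 * 500L),
              mk_markers(ref = "refB", partner = "p2", pos_b = 1:5 * 500L))
  res2 <- build_blocks(build_tracks(m2, character(), character()))
  expect_equal(nrow(link_scaffolds(res2$blocks)), 0L)

  # conflicting proposals: the better-supported link wins
  m3 <- rbind(mk_markers(ref = "refA", partner = "p1", pos_b = 1:5 * 500L,
                         pos_a = 1:5 * 1000L),
              mk_markers(ref = "refB", partner = "p1", pos_b = 6:10 * 500L,
                         pos_a = 1:5 * 1000L),
              mk_markers(ref = "refA", partner = "p2", pos_b = 1:2 * 500L,
                         pos_a = 6:7 * 1000L),
              mk_markers(ref = "refC", partner = "p2", pos_b = 3:4 * 500L,
                         pos_a = 1:2 * 1000L))
  res3 <- build_blocks(build_tracks(m3, character(), character()))
  links3 <- link_scaffolds(res3$blocks)
  expect_true(any(links3$ref_a == "refA" & links3$ref_b == "refB" |
                  links3$ref_a == "refB" & links3$ref_b == "refA"))
})

test_that("unplaced scaffolds are placed only with enough consecutive support", {
  maps_r <- c(r1 = "LG1")   # r_un absent -> unplaced
  map_p <- c(p1 = "c1")
  base <- mk_markers(ref = "r1", partner = "p1",
                     pos_b = c(1:5 * 1000L, 20:24 * 1000L),
                     pos_a = 1:10 * 1000L)
  # unplaced scaffold with 3 consecutive markers in the partner gap
  un3 <- mk_markers(ref = "r_un", partner = "p1",
                    pos_b = c(8000L, 10000L, 12000L), pos_a = 1:3 * 100L)
  res <- build_blocks(build_tracks(rbind(base, un3), maps_r, map_p))
  placed <- place_unplaced(res$blocks, res$markers)
  expect_equal(placed$placed_chrom[placed$ref_scaffold == "r_un"], "LG1")
  # only 2 supporting markers -> not placed
  un2 <- un3[1:2, ]
  res2 <- build_blocks(build_tracks(rbind(base, un2), maps_r, map_p))
  placed2 <- place_unplaced(res2$blocks, res2$markers)
  expect_true(is.na(placed2$placed_chrom[placed2$ref_scaffold == "r_un"]))
})

test_that("synteny summary arithmetic", {
  blocks <- data.frame(
    ref_scaffold = "r1", ref_start = c(0, 4e6, 10e6) ,
    ref_end = c(2e6, 8e6, 16e6), partner_scaffold = "p1",
    partner_start = c(0, 4e6, 10e6), partner_end = c(2e6, 8e6, 16e6),
    orientation = "+", n_markers = 5L, ref_chrom = "LG1",
    partner_chrom = "c1", block_id = 1:3)
  ev <- classify_rearrangements(blocks[0, ])
  s <- summarize_synteny(blocks, ev)
  expect_equal(s$n_blocks, 3L)
  expect_equal(s$ref$mean, 4e6)
  expect_equal(s$ref$median, 4e6)
  expect_equal(s$ref$total, 12e6)
  expect_equal(s$n_large_blocks, 1L)
  s0 <- summarize_synteny(blocks[0, ], ev)
  expect_equal(s0$n_blocks, 0L)
})
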