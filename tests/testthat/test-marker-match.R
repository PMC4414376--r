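make_locus_table <- function(...) {
  # loci as list(left, right, motif); coordinates are dummies
  args <- list(...)
  data.frame(scaffold = "s", start = seq_along(args) * 1000L,
             end = seq_along(args) * 1000L + 20L,
             motif = vapply(args, `[[`, "", 3L),
             motif_len = 2L, n_units = 10L,
             locus_id = paste0("s:", seq_along(args) * 1000L),
             left_flank = vapply(args, `[[`, "", 1L),
             right_flank = vapply(args, `[[`, "", 2L),
             usable = TRUE, stringsAsFactors = FALSE)
}

test_that("flank_identity: identical, mutated, and reverse-complement flanks", {
  set.seed(10)
  l <- random_seq(200); r <- random_seq(200)
  fi <- flank_identity(l, r, l, r)
  expect_equal(fi$identity, 1.0)
  expect_equal(fi$orientation, "+")
  expect_equal(fi$aligned_fraction, 1.0)

  # one substitution in 400 aligned bp
  l2 <- l
  substr(l2, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                  substr(l, 100, 100))[1L]
  fi <- flank_identity(l, r, l2, r)
  expect_equal(fi$identity, 399 / 400)

  # strand flip: partner flanks are reverse-complemented and swapped
  fi <- flank_identity(l, r, revcomp(r), revcomp(l))
  expect_equal(fi$identity, 1.0)
  expect_equal(fi$orientation, "-")

  expect_error(flank_identity("", "", l, r), "empty flanks")
})

test_that("match_markers accepts true pairs and rejects mutated/tied ones", {
  set.seed(11)
  fl <- replicate(6, list(random_seq(200), random_seq(200), "AC"),
                  simplify = FALSE)
  a <- do.call(make_locus_table, fl)
  # partner: loci 1-4 identical, locus 5 mutated to ~0.80 identity
  flb <- fl
  mut <- strsplit(flb[[5L]][[1L]], "")[[1L]]
  idx <- sample(200, 80)
  mut[idx] <- sample(c("A", "C", "G", "T"), 80, replace = TRUE)
  flb[[5L]][[1L]] <- paste(mut, collapse = "")
  flb[[6L]] <- flb[[5L]]  # unused filler with same flanks as 5 -> tie risk
  b <- do.call(make_locus_table, fl[1:4])
  pairs <- match_markers(a, b)
  expect_equal(nrow(pairs), 4L)
  expect_true(all(pairs$identity == 1))
  expect_true(all(pairs$orientation == "+"))

  # identity ~0.80 with min_identity 0.90 -> unmatched
  b5 <- do.call(make_locus_table, flb[5L])
  a5 <- do.call(make_locus_table, fl[5L])
  pairs <- match_markers(a5, b5)
  expect_equal(nrow(pairs), 0L)

  # two B loci with identical flanks best-hitting one A locus -> all dropped
  a1 <- do.call(make_locus_table, fl[1L])
  b_tie <- do.call(make_locus_table, fl[1L], )
  b_tie2 <- rbind(b_tie, transform(b_tie, start = 9000L, locus_id = "s:9000"))
  pairs <- match_markers(a1, b_tie2)
  expect_equal(nrow(pairs), 0L)
})

test_that("matching is one-to-one and symmetric", {
  set.seed(12)
  sim <- simulate_assembly_pair(sim_params(
    genome_size = 1e6, n_chromosomes = 2, ssr_per_mb = 40,
    markers_per_event = 5L, event_buffer_markers = 1L,
    n_inversions = 1, n_translocations = 0, seed = 12))
  p <- ssr_params()
  la <- extract_flanks(find_assembly_ssrs(sim$a$assembly, p), sim$a$assembly, p)
  lb <- extract_flanks(find_assembly_ssrs(sim$b$assembly, p), sim$b$assembly, p)
  ab <- match_markers(la, lb)
  expect_false(any(duplicated(ab$locus_a)))
  expect_false(any(duplicated(ab$locus_b)))
  ba <- match_markers(lb, la)
  expect_setequal(paste(ab$locus_a, ab$locus_b),
                  paste(ba$locus_b, ba$locus_a))
})

test_that("matching at zero mutation rate recovers every usable locus exactly", {
  sim <- simulate_assembly_pair(sim_params(
    genome_size = 1e6, n_chromosomes = 2, ssr_per_mb = 30, mu = 0,
    indel_rate = 0, n_inversions = 0, n_translocations = 0, seed = 13))
  p <- ssr_params()
  la <- extract_flanks(find_assembly_ssrs(sim$a$assembly, p), sim$a$assembly, p)
  lb <- extract_flanks(find_assembly_ssrs(sim$b$assembly, p), sim$b$assembly, p)
  pairs <- match_markers(la, lb)
  em <- evaluate_matches(pairs, sim)
  expect_equal(em$recall, 1.0)
  expect_equal(em$precision, 1.0)
  expect_true(all(pairs$identity == 1.0))
})

test_that("recall >= 95% and precision >= 99% at 2% flank divergence", {
  recs <- precs <- numeric(3)
  for (i in 1:3) {
    sim <- simulate_assembly_pair(sim_params(
      genome_size = 2e6, n_chromosomes = 2, ssr_per_mb = 40, mu = 0.02,
      n_inversions = 0, n_translocations = 0, seed = 100 + i))
    p <- ssr_params()
    la <- extract_flanks(find_assembly_ssrs(sim$a$assembly, p), sim$a$assembly, p)
    lb <- extract_flanks(find_assembly_ssrs(sim$b$assembly, p), sim$b$assembly, p)
    em <- evaluate_matches(match_markers(la, lb), sim)
    recs[i] <- em$recall; precs[i] <- em$precision
  }
  expect_true(all(recs >= 0.95))
  expect_true(all(precs >= 0.99))
})
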