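small_params <- function(...) {
  sim_params(genome_size = 1e6, n_chromosomes = 2, ssr_per_mb = 60,
             markers_per_event = 5L, event_buffer_markers = 1L, ...)
}

test_that("generators are reproducible under a fixed seed", {
  s1 <- simulate_assembly_pair(small_params(n_inversions = 1,
                                            n_translocations = 1, seed = 40))
  s2 <- simulate_assembly_pair(small_params(n_inversions = 1,
                                            n_translocations = 1, seed = 40))
  expect_identical(s1$a$assembly$seq, s2$a$assembly$seq)
  expect_identical(s1$b$assembly$seq, s2$b$assembly$seq)
  expect_identical(s1$events, s2$events)
  d1 <- simulate_domain_tables(n_genes = 200, seed = 41)
  d2 <- simulate_domain_tables(n_genes = 200, seed = 41)
  expect_identical(d1$focal, d2$focal)
  m1 <- simulate_methylome(n_genes = 20, seed = 42)
  m2 <- simulate_methylome(n_genes = 20, seed = 42)
  expect_identical(m1$genes, m2$genes)
})

test_that("the ancestor carries the stated number of detectable loci", {
  p <- small_params(seed = 43)
  anc <- local({ set.seed(43); simulate_ancestor(p) })
  expect_equal(nrow(anc$loci), 60)
  # every implanted locus is recovered exactly by the scanner
  found <- find_ssrs(anc$chroms[["chr1"]])
  tr <- anc$loci[anc$loci$chrom == "chr1", ]
  hits <- merge(tr, found, by = c("start", "end", "motif", "n_units"))
  expect_equal(nrow(hits), nrow(tr))
  expect_error(simulate_ancestor(sim_params(genome_size = 1e5,
                                            n_chromosomes = 1,
                                            ssr_per_mb = 2000)),
               "density too high")
})

test_that("identity limit: mu = 0, no rearrangements gives B identical to A", {
  sim <- simulate_assembly_pair(small_params(mu = 0, indel_rate = 0,
                                             n_inversions = 0,
                                             n_translocations = 0, seed = 44))
  expect_identical(unname(sim$a$assembly$seq), unname(sim$b$assembly$seq))
  expect_identical(sim$pairs$start_a, sim$pairs$start_b)
})

test_that("the event history has the stated composition and valid breakpoints", {
  sim <- simulate_assembly_pair(small_params(n_inversions = 2,
                                             n_translocations = 2, seed = 45))
  expect_equal(sum(sim$events$type == "inversion"), 2L)
  expect_equal(sum(sim$events$type == "translocation"), 2L)
  expect_true(all(sim$events$start < sim$events$end))
  tr <- setdiff(sim$events$dest_chrom[sim$events$type == "translocation"], NA)
  expect_false(any(tr == sim$events$chrom[sim$events$type == "translocation"]))
})

test_that("flank mismatch fraction matches mu", {
  p <- small_params(mu = 0.01, indel_rate = 0, n_inversions = 0,
                    n_translocations = 0, seed = 46)
  sim <- simulate_assembly_pair(p)
  # compare 200 bp upstream of each truth locus between the assemblies
  mism <- total <- 0
  for (i in seq_len(nrow(sim$pairs))) {
    fa <- substr(sim$a$assembly$seq[[sim$pairs$scaffold_a[i]]],
                 sim$pairs$start_a[i] - 199, sim$pairs$start_a[i])
    fb <- substr(sim$b$assembly$seq[[sim$pairs$scaffold_b[i]]],
                 sim$pairs$start_b[i] - 199, sim$pairs$start_b[i])
    ca <- strsplit(fa, "")[[1L]]; cb <- strsplit(fb, "")[[1L]]
    mism <- mism + sum(ca != cb); total <- total + length(ca)
  }
  expect_lt(abs(mism / total - p$mu), 3 * sqrt(p$mu / total) + 1e-3)
})

test_that("lifted truth coordinates point at the right sequence", {
  sim <- simulate_assembly_pair(small_params(n_inversions = 2,
                                             n_translocations = 1, seed = 47))
  for (side in c("a", "b")) {
    d <- sim[[side]]
    for (i in seq_len(nrow(d$loci))) {
      seq <- substr(d$assembly$seq[[d$loci$scaffold[i]]],
                    d$loci$start[i] + 1L, d$loci$end[i])
      # the lifted interval holds a perfect repeat of the canonical motif
      det <- find_ssrs(seq, ssr_params(min_units = rep(2L, 6L)))
      expect_true(nrow(det) >= 1L && det$start[1L] == 0L,
                  info = paste(side, i))
    }
  }
})

test_that("unlift_position inverts the coordinate maps", {
  sim <- simulate_assembly_pair(small_params(n_inversions = 2,
                                             n_translocations = 1,
                                             gaps_per_mb = 3, breaks_per_mb = 2,
                                             seed = 48))
  for (side in c("a", "b")) {
    d <- sim[[side]]
    loci <- d$loci
    anc <- unlift_position(d, loci$scaffold, loci$start)
    anc_truth <- sim$ancestor$loci[match(loci$anc_id,
                                         sim$ancestor$loci$anc_id), ]
    expect_equal(anc$anc_chrom, anc_truth$chrom)
    fwd <- loci$strand == "+"
    expect_equal(anc$anc_pos[fwd], anc_truth$start[fwd])
    # a minus-strand locus start maps to the ancestor interval's last base
    expect_equal(anc$anc_pos[!fwd], anc_truth$end[!fwd] - 1L)
  }
})

test_that("fragmentation with N gaps yields multi-scaffold assemblies", {
  sim <- simulate_assembly_pair(small_params(gaps_per_mb = 5, breaks_per_mb = 3,
                                             n_inversions = 0,
                                             n_translocations = 0, seed = 49))
  expect_gt(length(sim$b$assembly$seq), 2L)
  expect_true(any(grepl("N", sim$b$assembly$seq)))
  # chromosome map still covers every scaffold
  expect_setequal(names(sim$b$chrom_map), names(sim$b$assembly$seq))
  expect_true(all(sim$b$chrom_map %in% c("chr1", "chr2")))
})

test_that("null domain tables have identical margins structure; effects implant", {
  dt <- simulate_domain_tables(n_genes = 300, n_domains = 50, seed = 50)
  expect_setequal(unique(dt$focal$domain) %in% sprintf("D%03d", 1:50), TRUE)
  dt2 <- simulate_domain_tables(
    n_genes = 300, n_domains = 50,
    effects = list(list(type = "expansion", domain = "D005", fold = 5),
                   list(type = "repeat_shift", domain = "D010", delta = 2)),
    seed = 50)
  cf <- count_domains(dt2$focal); cr <- count_domains(dt2$ref)
  expect_gt(cf[["D005"]], 2.5 * cr[["D005"]])
  rn <- compare_repeat_numbers(dt2$focal, dt2$ref)
  expect_true(any(rn$disjoint & rn$domain == "D010"))
})

test_that("methylome generator hits its class targets", {
  mm <- simulate_methylome(n_genes = 60, targets = c(0.5, 1.2),
                           class_props = c(0.3, 0.7), seed = 51)
  oe <- vapply(mm$genes, cpg_oe, numeric(1))
  expect_lt(abs(mean(oe[mm$labels == 1]) - 0.5), 0.05)
  expect_lt(abs(mean(oe[mm$labels == 2]) - 1.2), 0.05)
  expect_error(simulate_methylome(n_genes = 5, targets = c(0.5, 9)),
               "not attainable")
  m1 <- simulate_methylome(n_genes = 10, class_props = 1, targets = 0.7,
                           seed = 52)
  expect_true(all(m1$labels == 1))
})
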