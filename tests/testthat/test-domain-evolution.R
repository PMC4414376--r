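hits_df <- function(gene, domain, ps, pe, ms, me) {
  data.frame(gene = gene, domain = domain, protein_start = ps,
             protein_end = pe, model_start = ms, model_end = me,
             stringsAsFactors = FALSE)
}

test_that("split hits over one model merge; full repeats do not", {
  # A[model 1-40] + A[model 41-80], adjacent on the protein -> one domain
  h <- hits_df("g1", "A", c(1, 60), c(50, 120), c(1, 41), c(40, 80))
  m <- collapse_consecutive(h)
  expect_equal(nrow(m), 1L)
  expect_equal(m$model_end, 80)
  expect_equal(m$protein_end, 120)

  # two full copies -> a true tandem repeat, kept separate
  h2 <- hits_df("g1", "A", c(1, 100), c(90, 190), c(1, 1), c(80, 80))
  expect_equal(nrow(collapse_consecutive(h2)), 2L)

  # [A, B, A]: non-adjacent same-domain hits unchanged
  h3 <- hits_df("g1", c("A", "B", "A"), c(1, 100, 200), c(90, 190, 290),
                c(1, 1, 1), c(80, 60, 80))
  expect_equal(collapse_consecutive(h3)$domain, c("A", "B", "A"))

  # a chain of three split hits collapses to one
  h4 <- hits_df("g1", "A", c(1, 40, 80), c(35, 75, 115),
                c(1, 31, 61), c(30, 60, 90))
  expect_equal(nrow(collapse_consecutive(h4)), 1L)

  # split coverage far apart on the protein is not merged
  h5 <- hits_df("g1", "A", c(1, 500), c(50, 560), c(1, 41), c(40, 80))
  expect_equal(nrow(collapse_consecutive(h5)), 2L)
})

test_that("count_domains counts once per gene, order-invariantly", {
  h <- hits_df(c("g1", "g1", "g1", "g2"), c("A", "A", "B", "A"),
               c(1, 100, 200, 1), c(80, 180, 280, 80),
               1, 80)
  expect_equal(count_domains(h), c(A = 2L, B = 1L))
  expect_equal(count_domains(h[sample(nrow(h)), ]), c(A = 2L, B = 1L))
  expect_equal(length(count_domains(h[0, ])), 0L)
  h6 <- hits_df("g1", "A", seq(1, 600, 100), seq(1, 600, 100) + 79, 1, 80)
  expect_equal(count_domains(h6), c(A = 1L))
})

test_that("unique_domains is a set difference against all references", {
  focal <- c(A = 3L, B = 1L)
  expect_equal(unique_domains(focal, list(c(A = 5L), c(A = 2L))), "B")
  expect_equal(unique_domains(c(A = 1L), list(c(A = 1L, B = 2L))),
               character())
  expect_error(unique_domains(focal, list()), "reference")
})

test_that("fisher_expansion_test equals hypergeometric enumeration", {
  expect_equal(fisher_expansion_test(5, 100, 5, 100), 1.0)
  expect_equal(fisher_expansion_test(3, 4, 1, 4), fisher_oracle(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_equal(fisher_expansion_test(0, 10, 10, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_expansion_test(1, 0, 1, 5), "positive")
  set.seed(20)
  for (i in 1:300) {
    tf <- sample(2:200, 1); tr <- sample(2:200, 1)
    cf <- sample(0:tf, 1); cr <- sample(0:tr, 1)
    expect_equal(fisher_expansion_test(cf, tf, cr, tr),
                 fisher_oracle(cf, tf - cf, cr, tr - cr),
                 tolerance = 1e-9, info = sprintf("%d/%d vs %d/%d", cf, tf, cr, tr))
  }
})

test_that("scan_expansions flags implanted contrasts with direction", {
  focal <- setNames(rep(10L, 50), sprintf("D%02d", 1:50))
  ref <- focal
  focal["D07"] <- 6L; ref["D07"] <- 22L   # contracted in focal
  res <- scan_expansions(focal, ref)
  expect_true("D07" %in% res$domain)
  expect_equal(res$direction[res$domain == "D07"], "contracted")
  expect_equal(nrow(scan_expansions(focal, focal)), 0L)

  # absent in focal, abundant in reference, on a broad shared background
  bg <- setNames(rep(20L, 40), sprintf("B%02d", 1:40))
  focal2 <- c(c(A = 0L), bg); ref2 <- c(c(A = 30L), bg)
  res2 <- scan_expansions(focal2, ref2)
  expect_true("A" %in% res2$domain)
  expect_equal(res2$direction[res2$domain == "A"], "contracted")
  expect_equal(res2$p[res2$domain == "A"],
               fisher_oracle(0, sum(focal2), 30, sum(ref2) - 30),
               tolerance = 1e-9)
})

test_that("repeat-number comparison respects the occurrence filters", {
  # arrangement {A}: sp1 counts {3,5}, sp2 {2,2} -> disjoint
  sp1 <- hits_df(c(rep("g1", 3), rep("g2", 5)), "A",
                 c(1, 100, 200, 1, 100, 200, 300, 400),
                 c(80, 180, 280, 80, 180, 280, 380, 480), 1, 80)
  sp2 <- hits_df(c("h1", "h1", "h2", "h2"), "A", c(1, 100, 1, 100),
                 c(80, 180, 80, 180), 1, 80)
  res <- compare_repeat_numbers(sp1, sp2)
  expect_equal(res$min1, 3L); expect_equal(res$max1, 5L)
  expect_equal(res$min2, 2L); expect_equal(res$max2, 2L)
  expect_true(res$disjoint)

  # arrangement occurring once per species -> excluded
  res2 <- compare_repeat_numbers(sp1[1:3, ], sp2[1:2, ])
  expect_equal(nrow(res2), 0L)

  # arrangement in only one species -> excluded
  sp2b <- hits_df("h1", "B", 1, 80, 1, 80)
  expect_equal(nrow(compare_repeat_numbers(sp1, sp2b)), 0L)
})
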