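test_that("the relative-difference statistic matches hand arithmetic", {
  em <- make_em(rbind(c(1, 2, 3, 1, 2, 3),
                      c(3, 5, 4, 1, 2, 0)),
                genes = c("flat", "shifted"),
                samples = sprintf("s%d", 1:6))
  lab <- rep(c(TRUE, FALSE), each = 3)
  st <- sam_statistics(em, lab, s0 = 0.1)
  expect_equal(st$d[st$gene_id == "flat"], 0)          # equal means
  sh <- st[st$gene_id == "shifted", ]
  expect_equal(sh$r, 3)
  expect_equal(sh$s, sqrt((1 / 3 + 1 / 3) * (2 + 2) / 4), tolerance = 1e-12)
  st0 <- sam_statistics(em, lab, s0 = 0)
  expect_equal(st0$d[2], 3 / 0.816496580927726, tolerance = 1e-9)
})

test_that("zero-variance genes error without a fudge factor and work with one", {
  em <- make_em(rbind(c(2, 2, 1, 1)), genes = "g", samples = sprintf("s%d", 1:4))
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_error(suppressWarnings(sam_statistics(em, lab, s0 = 0)), "s0")
  st <- suppressWarnings(sam_statistics(em, lab, s0 = 1))
  expect_equal(st$d, 1.0)  # (2 - 1) / (0 + 1)
})

test_that("d is antisymmetric under swapping the class labels", {
  set.seed(31)
  em <- make_em(matrix(rnorm(200), 20, 10),
                genes = sprintf("g%d", 1:20), samples = sprintf("s%d", 1:10))
  lab <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(sam_statistics(em, lab, s0 = 0.2)$d,
               -sam_statistics(em, !lab, s0 = 0.2)$d)
})

test_that("with s0 = 0 the statistic equals the pooled-variance t statistic", {
  set.seed(32)
  em <- make_em(matrix(rnorm(1000 * 12), 1000, 12),
                genes = sprintf("g%d", 1:1000), samples = sprintf("s%d", 1:12))
  lab <- rep(c(TRUE, FALSE), each = 6)
  d <- sam_statistics(em, lab, s0 = 0)$d
  t_ref <- apply(em$values, 1, function(x) {
    stats::t.test(x[lab], x[!lab], var.equal = TRUE)$statistic
  })
  expect_equal(d, unname(t_ref), tolerance = 1e-10)
})

test_that("fudge-factor selection lands at zero when spread is independent of s", {
  set.seed(33)
  s <- runif(1000, 0.1, 2)
  r <- s * rnorm(1000)  # d = r/s has s-independent spread at s0 = 0
  s0 <- choose_s0(r, s)
  expect_lte(mean(s < s0), 0.01)  # at (or below) the 0th percentile of s
})

test_that("fudge-factor selection warns on small panels but still returns", {
  set.seed(34)
  s <- runif(50, 0.5, 1)
  r <- rnorm(50)
  expect_warning(s0 <- choose_s0(r, s), "100 genes")
  expect_true(is.finite(s0) && s0 >= 0)
  # identical standard errors: degenerate, returns 0 with a warning
  expect_warning(z <- choose_s0(rnorm(200), rep(0.7, 200)), "identical")
  expect_equal(z, 0)
  # deterministic across calls
  expect_identical(suppressWarnings(choose_s0(r, s)),
                   suppressWarnings(choose_s0(r, s)))
})

test_that("permutation machinery is reproducible and exhaustive at small n", {
  set.seed(35)
  em <- make_em(matrix(rnorm(100 * 8), 100, 8),
                genes = sprintf("g%d", 1:100), samples = sprintf("s%d", 1:8))
  lab <- rep(c(TRUE, FALSE), each = 4)
  a <- suppressWarnings(sam_call(em, lab, n_permutations = 500, seed = 7))
  b <- suppressWarnings(sam_call(em, lab, n_permutations = 500, seed = 7))
  expect_identical(a$table, b$table)
  expect_true(a$exhaustive)                     # C(8,4) = 70 <= 500
  expect_equal(a$n_permutations_used, choose(8, 4))
  # exhaustive enumeration makes the seed irrelevant
  c <- suppressWarnings(sam_call(em, lab, n_permutations = 500, seed = 99))
  expect_identical(a$table, c$table)
})

test_that("expected order statistics converge to the observed on null data", {
  set.seed(36)
  em <- make_em(matrix(rnorm(300 * 10), 300, 10),
                genes = sprintf("g%d", 1:300), samples = sprintf("s%d", 1:10))
  lab <- rep(c(TRUE, FALSE), each = 5)
  few <- sam_call(em, lab, n_permutations = 20, seed = 1)
  many <- sam_call(em, lab, n_permutations = 252, seed = 1)  # exhaustive
  expect_lt(mean(abs(many$d_sorted - many$dbar)),
            mean(abs(few$d_sorted - few$dbar)) + 0.02)
  expect_lt(mean(abs(many$d_sorted - many$dbar)), 0.2)
})

test_that("the called set shrinks as delta grows", {
  set.seed(37)
  v <- matrix(rnorm(500 * 12), 500, 12)
  v[1:20, 1:6] <- v[1:20, 1:6] + 2
  em <- make_em(v, genes = sprintf("g%d", 1:500), samples = sprintf("s%d", 1:12))
  lab <- rep(c(TRUE, FALSE), each = 6)
  obs <- sam_statistics(em, lab)
  s0 <- attr(obs, "s0")
  run <- sam_call(em, lab, n_permutations = 200, seed = 2, s0 = s0)
  # re-scan the delta grid through the public interface at coarser targets
  counts <- vapply(c(0.5, 0.25, 0.10, 0.02), function(tgt) {
    sam_call(em, lab, fdr_target = tgt, n_permutations = 200, seed = 2, s0 = s0)$n_called
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gte(run$n_called, 15)  # the planted block is found
})

test_that("planted signature genes are called at the 10% FDR target", {
  co <- simulate_cohort(cohort_spec(seed = 41))
  calls <- response_calls(co$dose_response)
  ext <- calls[calls$response_class %in% c("RESPONDER", "NON_RESPONDER"), ]
  sub <- subset_expression(co$expression, samples = ext$sample_id)
  run <- sam_call(sub, factor(ext$response_class,
                              levels = c("RESPONDER", "NON_RESPONDER")),
                  fdr_target = 0.10, n_permutations = 500, seed = 41)
  tab <- run$table
  expect_true(all(tab$called[tab$gene_id %in% planted_genes]))
  expect_true(all(tab$q_value[tab$gene_id %in% planted_genes] <= 0.10))
  # positive d means higher in responders (class 1)
  expect_true(all(tab$d[tab$gene_id %in% planted_genes] > 0))
})

test_that("the diagnostic plot is written to the requested path", {
  set.seed(38)
  em <- make_em(matrix(rnorm(100 * 8), 100, 8),
                genes = sprintf("g%d", 1:100), samples = sprintf("s%d", 1:8))
  run <- suppressWarnings(sam_call(em, rep(c(TRUE, FALSE), each = 4),
                                   n_permutations = 70, seed = 1))
  p <- withr::local_tempfile(fileext = ".png")
  sam_plot(run, p)
  expect_true(file.exists(p) && file.size(p) > 0)
})
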