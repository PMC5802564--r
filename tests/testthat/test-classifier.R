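test_that("Response Averages are midpoints of the extreme group means", {
  m <- fit_demo_model()
  # responder mean 8.1, non-responder mean 3.9 for CD19 -> RA = 6
  expect_equal(unname(m$ra["CD19"]), 6)
  expect_equal(unname(m$ra["BLNK"]), 6)
  expect_equal(m$score_threshold, 3L)
})

test_that("pooled averaging differs from midpoint under class imbalance", {
  genes <- c("g1", "g2")
  em <- make_em(rbind(c(8, 8, 8, 2), c(8, 8, 8, 2)), genes, sprintf("s%d", 1:4))
  calls <- data.frame(sample_id = sprintf("s%d", 1:4),
                      response_class = c(rep("RESPONDER", 3), "NON_RESPONDER"))
  mid <- suppressWarnings(fit_ra_model(em, calls, "g1", "g2", score_threshold = 1))
  pooled <- suppressWarnings(fit_ra_model(em, calls, "g1", "g2", score_threshold = 1,
                                          ra_method = "pooled"))
  expect_equal(unname(mid$ra["g1"]), 5)      # (8 + 2) / 2
  expect_equal(unname(pooled$ra["g1"]), 6.5) # (8*3 + 2) / 4
})

test_that("model fitting validates its inputs", {
  m <- fit_demo_model()
  em <- make_em(matrix(5, 2, 2), c("CD19", "EBF1"), c("a", "b"))
  calls <- data.frame(sample_id = c("a", "b"),
                      response_class = c("RESPONDER", "NON_RESPONDER"))
  expect_error(fit_ra_model(em, calls, "CD19", c("CD19", "EBF1")), "gate gene")
  expect_error(fit_ra_model(em, calls, "CD19", "PAX5"), "missing")
  calls$response_class <- c("RESPONDER", "RESPONDER")
  expect_error(suppressWarnings(fit_ra_model(em, calls, "CD19", "EBF1",
                                             score_threshold = 1)),
               "non-empty")
})

test_that("prediction applies the gate and the score rule literally", {
  m <- fit_demo_model()
  profile <- function(cd19, others) {
    make_em(matrix(c(cd19, others, 5), ncol = 1),
            c("CD19", "EBF1", "PAX5", "BTK", "BLNK", "GENE1"), "x")
  }
  # all five genes above their RAs -> responder
  hi <- predict(m, profile(7, rep(7, 4)))
  expect_true(hi$gate_passed)
  expect_equal(hi$score, 4L)
  expect_equal(hi$predicted, "Responder")
  expect_equal(hi$rule_fired, "pass")
  # gate gene low: immediate non-responder however high the rest
  gated <- predict(m, profile(5, rep(12, 4)))
  expect_false(gated$gate_passed)
  expect_equal(gated$score, 0L)
  expect_equal(gated$predicted, "NonResponder")
  expect_equal(gated$rule_fired, "gate")
  # gate passes, two secondary genes high: score 2 < 3 -> non-responder
  two <- predict(m, profile(7, c(7, 7, 5, 5)))
  expect_equal(two$score, 2L)
  expect_equal(two$predicted, "NonResponder")
  expect_equal(two$rule_fired, "score")
  # equality with an RA does not count as exceeding it
  eq <- predict(m, profile(6, rep(7, 4)))
  expect_false(eq$gate_passed)
  eq2 <- predict(m, profile(7, c(6, 7, 7, 5)))
  expect_equal(eq2$score, 2L)
})

test_that("the gate dominates: low gate expression always means non-responder", {
  m <- fit_demo_model()
  set.seed(61)
  n <- 10000
  v <- matrix(runif(6 * n, 0, 14), 6, n,
              dimnames = list(c("CD19", "EBF1", "PAX5", "BTK", "BLNK", "GENE1"),
                              sprintf("p%05d", seq_len(n))))
  v["CD19", ] <- runif(n, 0, m$ra["CD19"])  # gate at or below its RA
  pred <- predict(m, expression_matrix(v, "test"))
  expect_true(all(pred$predicted == "NonResponder"))
  expect_true(all(pred$rule_fired == "gate"))
})

test_that("prediction is monotone in every gene", {
  m <- fit_demo_model()
  set.seed(62)
  gene_ids <- c("CD19", "EBF1", "PAX5", "BTK", "BLNK", "GENE1")
  for (i in 1:200) {
    x <- runif(6, 2, 10)
    base <- make_em(matrix(x, ncol = 1), gene_ids, "x")
    p0 <- predict(m, base)$predicted
    bump <- x + runif(6, 0, 4) * rbinom(6, 1, 0.5)
    p1 <- predict(m, make_em(matrix(bump, ncol = 1), gene_ids, "x"))$predicted
    if (p0 == "Responder") expect_equal(p1, "Responder")
  }
})

test_that("confusion-matrix metrics match the printed operating point", {
  # a matrix with tp=15, fn=4, tn=44, fp=15 reproduces sensitivity 78.9%
  # and specificity 74.6%
  pred <- data.frame(
    sample_id = sprintf("s%d", 1:78),
    predicted = rep(c("Responder", "NonResponder", "NonResponder", "Responder"),
                    c(15, 4, 44, 15)))
  truth <- data.frame(
    sample_id = sprintf("s%d", 1:78),
    class = rep(c("Responder", "Responder", "NonResponder", "NonResponder"),
                c(15, 4, 44, 15)))
  m <- evaluate_predictions(pred, truth)
  expect_equal(m$tp, 15); expect_equal(m$fn, 4)
  expect_equal(m$tn, 44); expect_equal(m$fp, 15)
  expect_equal(round(100 * m$sensitivity, 1), 78.9)
  expect_equal(round(100 * m$specificity, 1), 74.6)
  expect_equal(m$accuracy, 59 / 78)
})

test_that("degenerate evaluations report absent ratios and id mismatches", {
  pred <- data.frame(sample_id = c("a", "b"),
                     predicted = c("NonResponder", "NonResponder"))
  truth <- data.frame(sample_id = c("a", "b"),
                      class = c("NonResponder", "NonResponder"))
  m <- evaluate_predictions(pred, truth)
  expect_true(is.na(m$sensitivity))   # no positive truth labels
  expect_equal(m$specificity, 1)
  expect_error(evaluate_predictions(pred, truth[1, , drop = FALSE]), "missing")
  perfect <- evaluate_predictions(
    data.frame(sample_id = c("a", "b"), predicted = c("Responder", "NonResponder")),
    data.frame(sample_id = c("a", "b"), class = c("Responder", "NonResponder")))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
})

test_that("normalization passes same-platform data through untouched", {
  co <- simulate_cohort(cohort_spec(n_samples = 20, seed = 63))
  calls <- response_calls(co$dose_response)
  m <- fit_ra_model(co$expression, calls, "CD19", c("EBF1", "PAX5", "BTK", "BLNK"))
  out <- normalize_to_reference(co$expression, m)
  expect_identical(out$values, co$expression$values)
})

test_that("quantile mapping undoes a monotone platform distortion", {
  co <- simulate_cohort(cohort_spec(seed = 64))
  calls <- response_calls(co$dose_response)
  m <- fit_ra_model(co$expression, calls, "CD19", c("EBF1", "PAX5", "BTK", "BLNK"))
  dist <- distort_platform(co$expression, gain = 1.2, offset = -1, noise_sd = 0)
  back <- normalize_to_reference(dist, m)
  expect_equal(back$platform, "normalized")
  for (j in seq_len(ncol(back$values))) {
    expect_equal(stats::cor(back$values[, j], co$expression$values[, j],
                            method = "spearman"), 1)
  }
  expect_lt(mean(abs(back$values - co$expression$values)), 0.05)
})

test_that("normalization rejects degenerate or foreign gene universes", {
  m <- fit_demo_model()
  single <- make_em(matrix(5, 1, 1), "CD19", "x", platform = "other")
  expect_error(normalize_to_reference(single, m), "single-gene")
  foreign <- make_em(matrix(rnorm(20), 10, 2),
                     sprintf("zz%d", 1:10), c("a", "b"), platform = "other")
  expect_error(normalize_to_reference(foreign, m), "10%")
})

test_that("the model file round-trips exactly", {
  m <- fit_demo_model()
  p <- withr::local_tempfile(fileext = ".txt")
  write_ra_model(m, p)
  back <- read_ra_model(p)
  expect_identical(back$gate_gene, m$gate_gene)
  expect_identical(back$secondary_genes, m$secondary_genes)
  expect_identical(back$score_threshold, m$score_threshold)
  expect_equal(back$ra, m$ra, tolerance = 0)
  expect_equal(back$reference_distribution, m$reference_distribution, tolerance = 0)
  expect_identical(back$training_genes, m$training_genes)
  # predictions from the reloaded model are identical
  co <- tiny_em()
  em <- make_em(matrix(runif(6 * 3, 2, 10), 6, 3),
                c("CD19", "EBF1", "PAX5", "BTK", "BLNK", "GENE1"),
                c("a", "b", "c"))
  expect_identical(predict(m, em), predict(back, em))
  expect_error(read_ra_model(withr::local_tempfile(lines = "junk")), "recognizable")
})
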