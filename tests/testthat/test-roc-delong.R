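test_that("AUROC equals hand-counted concordant pairs on small examples", {
  # females {2, 4}, males {1, 3}: 3 of 4 pairs concordant
  r <- roc_auc(c(2, 4, 1, 3), c("female", "female", "male", "male"))
  expect_equal(r$auroc, 0.75)

  # perfect separation
  expect_equal(roc_auc(c(5, 6, 1, 2), rep(c("female", "male"), each = 2))$auroc, 1)

  # all scores tied
  expect_equal(roc_auc(rep(1, 6), rep(c("female", "male"), 3))$auroc, 0.5)

  expect_error(roc_auc(1:3, rep("female", 3)), "both classes")
})

test_that("AUROC identities hold on random tied inputs", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    scores <- sample(round(rnorm(n), 1))   # heavy ties
    labels <- sample(rep(c("female", "male"), length.out = n))
    r <- roc_auc(scores, labels)
    # pair-counting identity (brute-force oracle)
    expect_equal(r$auroc, auroc_oracle(scores, labels), tolerance = 1e-12)
    # trapezoidal area under the tie-aware curve
    expect_equal(r$auroc, trapezoid_area(r$roc$fpr, r$roc$tpr),
                 tolerance = 1e-12)
    # complement symmetry
    expect_equal(roc_auc(-scores, labels)$auroc, 1 - r$auroc,
                 tolerance = 1e-12)
    # curve is monotone nondecreasing
    expect_true(all(diff(r$roc$tpr) >= 0) && all(diff(r$roc$fpr) >= 0))
  }
})

test_that("paired DeLong handles degenerate and antisymmetric cases", {
  labels <- rep(c("female", "male"), 10)
  set.seed(62)
  a <- rnorm(20); b <- rnorm(20)

  same <- delong_paired(a, a, labels)
  expect_equal(same$delta_auroc, 0)
  expect_equal(same$p_value, 1)

  ab <- delong_paired(a, b, labels)
  ba <- delong_paired(b, a, labels)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("paired DeLong agrees with pROC on random data", {
  set.seed(63)
  for (i in 1:5) {
    n <- 80
    labels <- rep(c("female", "male"), each = n / 2)
    base <- rnorm(n, ifelse(labels == "female", 0.8, 0))
    a <- base + rnorm(n, sd = 0.7)
    b <- base + rnorm(n, sd = 0.9)
    got <- delong_paired(a, b, labels)
    ref <- pROC::roc.test(
      pROC::roc(labels, a, levels = c("male", "female"), direction = "<",
                quiet = TRUE),
      pROC::roc(labels, b, levels = c("male", "female"), direction = "<",
                quiet = TRUE),
      method = "delong", paired = TRUE
    )
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(got$auroc_a - got$auroc_b,
                 unname(ref$estimate[1] - ref$estimate[2]), tolerance = 1e-12)
  }
})

test_that("DeLong p-values are approximately uniform under the paired null", {
  set.seed(64)
  p <- vapply(1:500, function(i) {
    n <- 60
    labels <- sample(rep(c("female", "male"), n / 2))
    shared <- rnorm(n)
    a <- shared + rnorm(n, sd = 0.8)
    b <- shared + rnorm(n, sd = 0.8)
    delong_paired(a, b, labels)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_error(holm_adjust(c(0.2, 1.4)), "0, 1")

  set.seed(65)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})
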