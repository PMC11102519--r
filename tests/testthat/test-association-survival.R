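test_that("univariate associations equal closed-form OLS", {
  # identity attribute
  y <- minmax_normalize(c(0.1, 0.9, 0.4, 0.7, 0.2, 0.55))
  res <- suppressWarnings(univariate_assoc(data.frame(self = y), y))
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)

  # 3-point exact line
  res3 <- suppressWarnings(univariate_assoc(data.frame(x = c(0, 1, 2)), c(0, 1, 2)))
  expect_equal(res3$estimate, 1, tolerance = 1e-12)

  # 6-point fixture vs the closed-form slope / t-test oracle
  x <- c(1, 2, 4, 5, 7, 9)
  yy <- c(0.2, 0.1, 0.5, 0.4, 0.9, 0.8)
  res6 <- univariate_assoc(data.frame(x = x), yy)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (yy - mean(yy))) / sxx
  fit_res <- yy - (mean(yy) - slope * mean(x)) - slope * x
  se <- sqrt(sum(fit_res^2) / 4 / sxx)
  p_oracle <- 2 * pt(-abs(slope / se), df = 4)
  expect_equal(res6$estimate, slope, tolerance = 1e-10)
  expect_equal(res6$p_value, p_oracle, tolerance = 1e-10)

  # slope unchanged by attribute translation; constant attribute skipped
  res_shift <- univariate_assoc(data.frame(x = x + 100), yy)
  expect_equal(res_shift$estimate, slope, tolerance = 1e-10)
  expect_warning(univariate_assoc(data.frame(x = x, flat = rep(1, 6)), yy),
                 "zero variance")
})

test_that("multivariate model separates orthogonal attributes and checks rank", {
  set.seed(12)
  n <- 50
  a1 <- rnorm(n)
  a2 <- rnorm(n)
  y <- a1 + rnorm(n, 0, 0.1)
  res <- multivariate_assoc(data.frame(a1 = a1, a2 = a2), y)
  expect_lt(res$p_value[res$term == "a1"], 1e-10)
  expect_gt(res$p_value[res$term == "a2"], 0.01)
  expect_error(multivariate_assoc(data.frame(a1 = a1, dup = a1), y),
               "rank-deficient")
  # single attribute reduces to the univariate estimate
  uni <- univariate_assoc(data.frame(a1 = a1), y)
  single <- multivariate_assoc(data.frame(a1 = a1, a2 = a2), y,
                               exclusions = "a2")
  expect_equal(single$estimate, uni$estimate, tolerance = 1e-12)
  expect_equal(attr(single, "excluded"), "a2")
})

test_that("signature score is a weighted log2-cpm sum, invariant to depth", {
  m <- matrix(c(1e6, 10, 20, 30), 2, 2,
              dimnames = list(c("gS", "gO"), c("s1", "s2")))
  one_gene <- matrix(c(5, 9), 1, 2, dimnames = list("gS", c("s1", "s2")))
  sc <- signature_score(cpm_normalize(one_gene), c(gS = 1))
  expect_equal(unname(sc), rep(log2(1e6 + 1), 2))

  cpm <- cpm_normalize(m)
  expect_equal(unname(signature_score(cpm, c(gS = 0, gO = 0))), c(0, 0))
  expect_warning(s2 <- signature_score(cpm, c(gS = 1, missing = 2)),
                 "absent")
  expect_equal(signature_score(cpm_normalize(m * 2), c(gS = 1, gO = -0.5)),
               signature_score(cpm, c(gS = 1, gO = -0.5)))
  expect_error(signature_score(cpm, c(nope = 1)), "no signature gene")
})

test_that("batch correction removes an additive shift and preserves grand means", {
  set.seed(4)
  base <- matrix(rnorm(5 * 4), 5, 4)
  shifted <- cbind(base, base + 3)
  batch <- rep(c("b1", "b2"), each = 4)
  corr <- batch_correct(shifted, batch)
  # the two batches become indistinguishable
  expect_equal(corr[, 1:4], corr[, 5:8], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowMeans(corr), rowMeans(shifted), tolerance = 1e-12)
  # identical batches are untouched
  same <- cbind(base, base)
  expect_equal(batch_correct(same, batch), same, tolerance = 1e-12)
  # explicit group-mean arithmetic oracle
  m <- matrix(c(1, 5, 2, 6, 10, 20, 30, 40), 2, 4)
  oracle <- m
  for (b in list(1:2, 3:4)) {
    dev <- rowMeans(m[, b]) - rowMeans(m)
    oracle[, b] <- m[, b] - dev
  }
  expect_equal(batch_correct(m, c("x", "x", "y", "y")), oracle,
               tolerance = 1e-12)
  expect_warning(batch_correct(m, rep("x", 4)), "single batch")
})

test_that("batch correction agrees with limma on a balanced design", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- matrix(rnorm(40), 5, 8)
  batch <- rep(c("b1", "b2"), each = 4)
  ours <- batch_correct(m, batch)
  ref <- limma::removeBatchEffect(m, batch = batch)
  # same up to per-feature constants (centering conventions differ)
  expect_equal(ours - rowMeans(ours), ref - rowMeans(ref),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("median split is deterministic with ties assigned low", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(unname(median_split(c(1, 2, 3))), c("low", "low", "high"))
  expect_error(median_split(c(2, 2, 2)), "constant")
})

test_that("log-rank statistic matches explicit O-E/V arithmetic", {
  st <- data.frame(time = c(1, 2, 3, 4), event = 1,
                   group = c("A", "A", "B", "B"))
  res <- km_logrank(st)
  # hand-computed hypergeometric terms over the 4 event times
  # t=1: O_A=1, E_A=2/4, V=(1*3*2*2)/(4^2*3); t=2: O_A=1, E_A=1/3,
  # V=(1*2*1*2)/(3^2*2); t=3, t=4: one group at risk, V=0
  O <- 2
  E <- 0.5 + 1 / 3
  V <- 12 / 48 + 4 / 18
  expect_equal(res$chisq, (O - E)^2 / V, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq((O - E)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$df, 1)
})

test_that("KM curves are proper survival functions and symmetry gives p = 1", {
  st <- data.frame(time = rep(c(1, 2, 5), 2), event = rep(c(1, 0, 1), 2),
                   group = rep(c("A", "B"), each = 3))
  res <- km_logrank(st)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  for (g in c("A", "B")) {
    est <- res$curves$estimate[res$curves$group == g]
    expect_true(all(diff(est) <= 1e-12))
    expect_true(all(est >= 0 & est <= 1))
  }
  # no censoring: KM equals the empirical survival function
  s1 <- generate_survival(rep(c("g1", "g2"), each = 30),
                          c(g1 = 1, g2 = 3), seed = 5)
  res1 <- km_logrank(s1)
  g1 <- res1$curves[res1$curves$group == "g1", ]
  t1 <- s1$time[s1$group == "g1"]
  emp <- vapply(g1$time, function(tt) mean(t1 > tt), numeric(1))
  expect_equal(g1$estimate, emp, tolerance = 1e-12)
  expect_error(km_logrank(data.frame(time = 1:3, event = 0,
                                     group = c("A", "A", "B"))),
               "no event")
})
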