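test_that("noncentral F quantile reduces to the central case and round-trips", {
  expect_equal(noncentral_f_quantile(0.95, 3, 10, 0), qf(0.95, 3, 10),
               tolerance = 1e-9)
  grid <- expand.grid(p = c(0.01, 0.05, 0.5, 0.95),
                      df1 = c(1, 3), df2 = c(8, 40),
                      ncp = c(0, 2.5, 18))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    q <- noncentral_f_quantile(g$p, g$df1, g$df2, g$ncp)
    expect_lt(abs(pf(q, g$df1, g$df2, ncp = g$ncp) - g$p), 1e-8)
  }
  expect_error(noncentral_f_quantile(0, 1, 10, 1))
  expect_error(noncentral_f_quantile(0.5, 1, 10, -1))
})

test_that("noncentral F quantile agrees with a simulation oracle", {
  set.seed(91)
  n <- 2e5
  for (par in list(c(1, 24, 3.56), c(2, 64, 18.3))) {
    draws <- (rchisq(n, par[1], ncp = par[3]) / par[1]) /
      (rchisq(n, par[2]) / par[2])
    for (p in c(0.05, 0.5)) {
      q_pkg <- noncentral_f_quantile(p, par[1], par[2], par[3])
      # compare via the empirical CDF at the computed quantile
      p_emp <- mean(draws < q_pkg)
      expect_lt(abs(p_emp - p), 4 * sqrt(p * (1 - p) / n))
    }
  }
})

test_that("pairwise equivalence verdicts behave at the extremes", {
  set.seed(101)
  x <- rnorm(20)
  r <- equivalence_t_test(x, x)
  expect_s3_class(r, "equivalence_result")
  expect_equal(r$statistic, 0)
  expect_true(r$equivalent)

  y <- rnorm(20)
  r2 <- equivalence_t_test(y, y + 3 * sd(y))  # ~3 pooled SDs apart
  expect_false(r2$equivalent)

  # degenerate zero pooled variance
  expect_message(r3 <- equivalence_t_test(rep(2, 5), rep(2, 6)), "degenerate")
  expect_true(r3$equivalent)
  expect_message(r4 <- equivalence_t_test(rep(2, 5), rep(3, 6)), "degenerate")
  expect_false(r4$equivalent)
  expect_error(equivalence_t_test(1, rnorm(5)))
})

test_that("k-group equivalence verdicts behave at the extremes", {
  set.seed(111)
  g <- rnorm(15)
  r <- equivalence_f_test(list(A = g, B = g, C = g))
  expect_true(r$equivalent)
  expect_lt(r$statistic, 1e-20)

  sdp <- 1
  r2 <- equivalence_f_test(list(A = rnorm(15), B = rnorm(15),
                                C = rnorm(15, mean = 5 * sdp)))
  expect_false(r2$equivalent)

  expect_message(r3 <- equivalence_f_test(list(rep(1, 4), rep(1, 4), rep(1, 4))),
                 "degenerate")
  expect_true(r3$equivalent)
  expect_error(equivalence_f_test(list(rnorm(3), c(1))), "at least 2 samples")
})

test_that("verdicts are monotone in the margin and in alpha", {
  set.seed(121)
  eps_grid <- c(0.3, 0.5, 0.74, 1.1, 1.6)
  for (rep in 1:10) {
    x <- rnorm(12, 0, 1)
    y <- rnorm(14, runif(1, 0, 1.2), 1)
    verdicts <- vapply(eps_grid, function(e)
      equivalence_t_test(x, y, epsilon = e)$equivalent, logical(1))
    crits <- vapply(eps_grid, function(e)
      equivalence_t_test(x, y, epsilon = e)$critical_value, numeric(1))
    expect_true(all(diff(crits) > 0))       # critical value grows with lambda
    expect_true(all(diff(as.integer(verdicts)) >= 0))  # never flips back
    averdicts <- vapply(c(0.01, 0.05, 0.2), function(a)
      equivalence_t_test(x, y, alpha = a)$equivalent, logical(1))
    expect_true(all(diff(as.integer(averdicts)) >= 0))
    g3 <- list(x, y, rnorm(10, 0.3))
    fverd <- vapply(eps_grid, function(e)
      equivalence_f_test(g3, epsilon = e)$equivalent, logical(1))
    expect_true(all(diff(as.integer(fverd)) >= 0))
  }
})

test_that("two-group F-test and t-test agree when noncentralities match", {
  set.seed(131)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    x <- rnorm(n); y <- rnorm(n, runif(1, 0, 1))
    eps_t <- 0.74
    # balanced two-group: lambda_t = eps_t^2 * n/2; lambda_F = 2n * eps_F^2
    eps_f <- eps_t / 2
    rt <- equivalence_t_test(x, y, epsilon = eps_t)
    rf <- equivalence_f_test(list(x, y), epsilon = eps_f)
    expect_equal(rf$statistic, rt$statistic^2, tolerance = 1e-10)
    expect_equal(rf$noncentrality, rt$noncentrality, tolerance = 1e-12)
    expect_equal(rf$critical_value, rt$critical_value^2, tolerance = 1e-8)
    expect_equal(rf$equivalent, rt$equivalent)
  }
})

test_that("declaring equivalence at the boundary stays near the alpha level", {
  set.seed(141)
  n <- 13; reps <- 1500
  hits <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(n); y <- rnorm(n, 0.74)
    if (equivalence_t_test(x, y)$equivalent) hits <- hits + 1L
  }
  rate <- hits / reps
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("Venn assignment picks the largest equivalent subset with tie-breaks", {
  set.seed(151)
  n <- 20
  # pathway 1: A and B identical (t = 0), C and D equivalent but noisier;
  # A/B far from C/D -> two disjoint pairs, no triple; A+B wins the tie-break
  ab <- rnorm(n)
  cd <- rnorm(n, 40)
  v1 <- c(ab, ab, cd, cd + 0.1 * sd(cd))
  # pathway 2: all four groups from one distribution
  v2 <- rnorm(4 * n)
  # pathway 3: all groups far apart -> unassigned
  v3 <- c(rnorm(n, 0), rnorm(n, 10), rnorm(n, 20), rnorm(n, 30))
  values <- rbind(p1 = v1, p2 = v2, p3 = v3)
  colnames(values) <- sprintf("s%02d", seq_len(4 * n))
  pas <- make_pas(values, rep(c("A", "B", "C", "D"), each = n))
  venn <- venn_similarity(pas, group_order = c("A", "B", "C", "D"))
  a <- venn$assignments
  expect_equal(a$region[a$pathway_id == "p1"], "A+B")
  expect_equal(a$region[a$pathway_id == "p2"], "A+B+C+D")
  expect_true(is.na(a$region[a$pathway_id == "p3"]))
  expect_equal(sum(venn$counts), sum(!is.na(a$region)))
  # direction tags follow the pooled mean sign
  expect_equal(a$direction[a$pathway_id == "p1"],
               if (mean(c(ab, ab)) > 0) "up" else "down")

  # JSON export mirrors the counts
  f <- tempfile(fileext = ".json")
  write_venn_json(venn, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$`A+B`$count, 1L)
  expect_equal(j$`A+B+C+D`$pathway_ids, "p2")
})

test_that("pathways drawn from one distribution concentrate in the full region", {
  set.seed(161)
  n <- 20; npw <- 60
  values <- matrix(rnorm(npw * 4 * n), npw, 4 * n,
                   dimnames = list(sprintf("pw%02d", 1:npw),
                                   sprintf("s%02d", 1:(4 * n))))
  pas <- make_pas(values, rep(c("W", "X", "Y", "Z"), each = n))
  venn <- venn_similarity(pas, group_order = c("W", "X", "Y", "Z"))
  full <- sum(venn$assignments$region == "W+X+Y+Z", na.rm = TRUE)
  expect_gt(full / npw, 0.8)
})

test_that("near-zero flags standardized small grand means in the full region", {
  set.seed(171)
  n <- 15
  v_zero <- rnorm(4 * n, 0, 1)
  v_off  <- rnorm(4 * n, 5, 1)   # 4-way equivalent but 5 SDs from zero
  values <- rbind(z = v_zero, o = v_off)
  colnames(values) <- sprintf("s%02d", 1:(4 * n))
  pas <- make_pas(values, rep(c("A", "B", "C", "D"), each = n))
  venn <- venn_similarity(pas, group_order = c("A", "B", "C", "D"))
  expect_equal(venn$assignments$region, rep("A+B+C+D", 2))
  expect_equal(near_zero_pathways(pas, venn), "z")
})
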