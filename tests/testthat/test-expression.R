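test_that("signed-rank test handles degenerate and extreme cases exactly", {
  same <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  # n = 8 pairs, all differences positive: two-sided p = 2 / 2^8
  res <- wilcoxon_signed_rank(rep(0, 8), 1:8)
  expect_equal(res$p_value, 2 / 256)
  expect_equal(res$statistic, 36)

  # one negative difference of smallest magnitude: equals 256-outcome
  # enumeration
  ctrl <- rep(0, 8)
  trt <- c(5, 4, 6, 7, 3, 8, 9, -0.5)
  expect_equal(wilcoxon_signed_rank(ctrl, trt)$p_value,
               brute_signed_rank(ctrl, trt)$p_value)
})

test_that("signed-rank p matches exhaustive enumeration for n <= 10", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(1:10, 1)
    ctrl <- round(rnorm(n), 1)
    trt <- round(ctrl + rnorm(n, sd = 1.5), 1)  # rounding induces ties/zeros
    got <- wilcoxon_signed_rank(ctrl, trt)
    want <- brute_signed_rank(ctrl, trt)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12,
                 label = paste("case", i))
  }
})

test_that("signed-rank agrees with stats::wilcox.test on tie-free data", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    ctrl <- rnorm(n)
    trt <- rnorm(n)
    got <- wilcoxon_signed_rank(ctrl, trt)
    ref <- stats::wilcox.test(trt, ctrl, paired = TRUE, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("call_degs recovers planted shifts with controlled false positives", {
  set.seed(55)
  n_pairs <- 8L
  vals <- matrix(rnorm(1000 * 16, sd = 0.5), 1000, 16)
  vals[1:50, 9:16] <- vals[1:50, 9:16] + 2
  rownames(vals) <- sprintf("g%04d", 1:1000)
  expr <- toy_expression(vals, n_pairs)
  degs <- call_degs(expr, regulon_config())
  shifted <- degs[1:50, ]
  expect_true(all(shifted$direction == "up"))
  # null genes: achievable alpha at n=8 is discrete; FP count stays within
  # 3 binomial SDs of 950 * alpha_achievable
  fp <- sum(degs$direction[51:1000] != "none")
  bound <- 950 * 0.05 + 3 * sqrt(950 * 0.05 * 0.95)
  expect_lt(fp, bound)
  expect_true(all(degs$adjusted_p >= degs$p_value - 1e-12))
})

test_that("all-null matrix keeps the type-I error near alpha", {
  set.seed(66)
  vals <- matrix(rnorm(950 * 16, sd = 0.5), 950, 16)
  rownames(vals) <- sprintf("n%04d", 1:950)
  degs <- call_degs(toy_expression(vals, 8L), regulon_config())
  fp <- sum(degs$direction != "none")
  # at n=8 the achievable two-sided levels below 0.05 are k/128
  expect_lt(fp, 950 * 0.05 + 3 * sqrt(950 * 0.05 * 0.95))
  empty <- call_degs(toy_expression(vals[0, , drop = FALSE], 8L))
  expect_equal(nrow(empty), 0L)
})

test_that("operon profiles are member means", {
  vals <- matrix(c(1, 2, 3, 4, -1, -2, -3, -4, 5, 5, 5, 5), 3, 4,
                 byrow = TRUE,
                 dimnames = list(c("a_g1", "a_g2", "b_g1"), NULL))
  expr <- toy_expression(vals, 2L)
  ops <- toy_operons(list(
    list(id = "a", strand = "+", starts = c(10, 100), ends = c(50, 140)),
    list(id = "b", strand = "+", starts = 200, ends = 240)))
  # locus tags in toy_operons are <id>_g<i>, matching rownames above
  prof <- operon_profiles(expr, ops)
  expect_equal(prof["a", ], colMeans(vals[1:2, ]), ignore_attr = TRUE)
  expect_equal(prof["b", ], vals[3, ], ignore_attr = TRUE)
  # opposite profiles cancel
  expect_equal(unname(prof["a", ]), c(0, 0, 0, 0))

  set.seed(3)
  vals10 <- matrix(rnorm(20 * 6), 20, 6)
  rownames(vals10) <- sprintf("op%02d_g%d", rep(1:10, each = 2), 1:2)
  expr10 <- toy_expression(vals10, 3L)
  ops10 <- toy_operons(purrr::map(1:10, ~ list(
    id = sprintf("op%02d", .x), strand = "+",
    starts = c(100, 200) + 1000 * .x, ends = c(150, 250) + 1000 * .x)))
  prof10 <- operon_profiles(expr10, ops10)
  for (i in 1:10) {
    expect_equal(prof10[sprintf("op%02d", i), ],
                 colMeans(vals10[(2 * i - 1):(2 * i), ]),
                 ignore_attr = TRUE)
  }
})

test_that("build_cems recovers planted blocks and applies size/singleton rules", {
  set.seed(21)
  centers <- matrix(rnorm(3 * 8, sd = 10), 3, 8)
  prof <- do.call(rbind, purrr::map(1:3, function(b)
    matrix(rep(centers[b, ], each = 10), 10, 8) + rnorm(80, sd = 0.3)))
  rownames(prof) <- sprintf("op%02d", 1:30)
  cems <- build_cems(prof, regulon_config())
  expect_equal(nrow(cems), 3L)
  expect_equal(sort(cems$size), c(10L, 10L, 10L))
  blocks <- purrr::map(1:3, ~ sprintf("op%02d", (10 * (.x - 1) + 1):(10 * .x)))
  for (b in blocks) {
    hit <- purrr::map_lgl(cems$operon_ids, ~ setequal(.x, b))
    expect_equal(sum(hit), 1L)
  }

  # partition invariant to row order
  perm <- sample(nrow(prof))
  cems2 <- build_cems(prof[perm, ], regulon_config())
  expect_equal(cems2$operon_ids, cems$operon_ids)

  # identical profiles pair off at distance zero
  prof3 <- rbind(prof, op98 = prof[1, ] + 100, op99 = prof[1, ] + 100)
  cems3 <- build_cems(prof3, regulon_config())
  hit <- purrr::map_lgl(cems3$operon_ids, ~ setequal(.x, c("op98", "op99")))
  expect_equal(sum(hit), 1L)
})

test_that("oversize clusters are removed and bookkeeping balances", {
  set.seed(77)
  # one tight block of 201 plus 20 scattered operons
  big <- matrix(rep(rnorm(8, sd = 10), each = 201), 201, 8) +
    rnorm(201 * 8, sd = 0.2)
  scatter <- matrix(rnorm(20 * 8, sd = 40), 20, 8)
  prof <- rbind(big, scatter)
  rownames(prof) <- sprintf("op%03d", seq_len(nrow(prof)))
  cems <- build_cems(prof, regulon_config())
  removed <- attr(cems, "removed_oversize")
  expect_equal(length(removed), 1L)
  expect_equal(length(removed[[1]]), 201L)
  expect_equal(sum(cems$size) + sum(lengths(removed)) +
                 length(attr(cems, "singletons")), nrow(prof))
  expect_error(build_cems(prof[1, , drop = FALSE]), "at least 2")
})
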