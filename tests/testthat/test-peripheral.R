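test_that("basic_stats: hand arithmetic, conventions, degenerate input", {
  s <- basic_stats(c(1, 2, 3))
  expect_equal(s[["mean"]], 2)
  expect_equal(s[["variance"]], 2 / 3)   # population
  expect_equal(s[["std"]], sqrt(2 / 3))
  expect_equal(s[["max"]], 3)
  expect_equal(s[["min"]], 1)
  expect_equal(s[["q50"]], 2)
  expect_equal(s[["skewness"]], 0)

  # constant signal: moments about a zero sd are defined as 0, not NaN
  k <- basic_stats(rep(4, 10))
  expect_equal(k[["skewness"]], 0)
  expect_equal(k[["kurtosis"]], 0)
  expect_equal(k[["variance"]], 0)

  # skewness antisymmetry
  set.seed(2)
  x <- rexp(200)
  expect_equal(basic_stats(x)[["skewness"]], -basic_stats(-x)[["skewness"]])

  # Monte-Carlo: standard normal excess kurtosis ~ 0
  set.seed(123)
  z <- rnorm(1e5)
  expect_lt(abs(basic_stats(z)[["kurtosis"]]), 0.1)
})

test_that("shift invariance and scale equivariance of the statistics", {
  set.seed(4)
  x <- rnorm(256)
  a <- basic_stats(x)
  b <- basic_stats(x + 10)
  for (nm in c("variance", "std", "skewness", "kurtosis"))
    expect_equal(b[[nm]], a[[nm]])
  for (nm in c("mean", "max", "min", "q25", "q50", "q75"))
    expect_equal(b[[nm]], a[[nm]] + 10)
  expect_equal(zero_crossing_rate(x + 10), zero_crossing_rate(x))
  expect_equal(approximate_entropy(x + 10), approximate_entropy(x))

  cc <- basic_stats(3 * x)
  expect_equal(cc[["std"]], 3 * a[["std"]])
  expect_equal(cc[["variance"]], 9 * a[["variance"]])
  expect_equal(cc[["skewness"]], a[["skewness"]])
  expect_equal(cc[["kurtosis"]], a[["kurtosis"]])
  expect_equal(zero_crossing_rate(3 * x), zero_crossing_rate(x))
})

test_that("zero-crossing rate counts strict sign changes after centring", {
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1)), 1)
  expect_equal(zero_crossing_rate(c(1, 2, 3, 4)), 1 / 3)  # centred ramp
  expect_equal(zero_crossing_rate(rep(5, 10)), 0)
  # zeros after centring inherit the previous sign: one crossing, not two
  expect_equal(zero_crossing_rate(c(-1, 0, 1)), 1 / 2)
})

test_that("approximate entropy: degenerate and periodic signals", {
  expect_equal(approximate_entropy(rep(1, 50)), 0)
  # strict alternation is perfectly predictable at m = 2 (up to the
  # finite-length template-count edge effect, which the oracle shares)
  x <- rep(c(1, 0), 50)
  got <- approximate_entropy(x, m = 2, r = 0.1)
  expect_lt(abs(got - oracle_apen(x, 2L, 0.1)), 1e-12)  # absolute: near 0
  expect_lt(abs(got), 1e-3)
})

test_that("approximate entropy equals the O(N^2) oracle", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    x <- rnorm(n)
    r <- 0.2 * sqrt(mean((x - mean(x))^2))
    expect_equal(approximate_entropy(x, m = 2, r = r),
                 oracle_apen(x, 2L, r), tolerance = 1e-12)
  }
  # default r path
  x <- rnorm(300)
  expect_equal(approximate_entropy(x),
               oracle_apen(x, 2L, 0.2 * sqrt(mean((x - mean(x))^2))),
               tolerance = 1e-12)
})

test_that("peripheral feature block has the documented size and order", {
  recs <- tiny_recordings()
  win <- slide_windows(recs[[1]]$trials[[1]], recs[[1]]$rate_hz)[[1]]
  block <- peripheral_feature_vector(win)
  expect_length(block, 96L)  # 12 stats x 8 channels
  expect_identical(names(block)[1:12],
                   paste0(rownames(win$peripheral)[1], "__",
                          emograph:::PERIPHERAL_STAT_NAMES))
  expect_false(anyDuplicated(names(block)) > 0)

  # one channel -> 12 features; duplicated channel -> identical sub-block
  win1 <- win
  win1$peripheral <- win$peripheral[1, , drop = FALSE]
  expect_length(peripheral_feature_vector(win1), 12L)
  win2 <- win
  win2$peripheral <- win$peripheral[c(1, 1), , drop = FALSE]
  rownames(win2$peripheral) <- c("a", "b")
  b2 <- peripheral_feature_vector(win2)
  expect_equal(unname(b2[1:12]), unname(b2[13:24]))
})
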