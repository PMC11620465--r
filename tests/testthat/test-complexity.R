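test_that("coarse-graining is block averaging with the floor-length law", {
  expect_equal(coarse_grain(1:6, 2), c(1.5, 3.5, 5.5))
  x <- rnorm(57)
  expect_equal(coarse_grain(x, 1), x)
  expect_length(coarse_grain(rnorm(10), 3), 3L)
  set.seed(2)
  for (tau in c(1, 2, 3, 5, 10, 57)) {
    y <- coarse_grain(x, tau)
    nblk <- 57 %/% tau
    expect_length(y, nblk)
    # mean preservation over the used prefix
    expect_equal(mean(y), mean(x[seq_len(nblk * tau)]))
  }
  expect_error(coarse_grain(1:5, 6), "length")
  expect_error(coarse_grain(1:5, 0), ">= 1")
})

test_that("sample entropy is zero for perfectly regular series", {
  expect_equal(as.numeric(sample_entropy(rep(3.7, 100), m = 2, r = 0.1)), 0)
  # strict alternation: every length-2 match continues deterministically
  x <- rep(c(0, 1), 60)
  expect_equal(as.numeric(sample_entropy(x, m = 2, r = 0.4)), 0)
})

test_that("optimized sample entropy equals the naive O(n^2) oracle", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(60:400, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                cumsum(rnorm(n)),
                sin(seq_len(n) / 5) + rnorm(n, sd = 0.3))
    m <- sample(1:3, 1)
    r <- runif(1, 0.05, 0.4) * sd(x)
    expect_identical(as.numeric(suppressWarnings(
                       sample_entropy(x, m = m, r = r))),
                     naive_sampen(x, m, r))
  }
})

test_that("euclidean metric option is stricter than chebyshev for m > 1", {
  set.seed(8)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  ch <- sample_entropy(x, m = 2, r = r, metric = "chebyshev")
  eu <- sample_entropy(x, m = 2, r = r, metric = "euclidean")
  expect_lt(attr(eu, "B"), attr(ch, "B"))
  # for m = 1 at template length 1 both metrics coincide on B
  ch1 <- sample_entropy(x, m = 1, r = r, metric = "chebyshev")
  eu1 <- sample_entropy(x, m = 1, r = r, metric = "euclidean")
  expect_equal(attr(ch1, "B"), attr(eu1, "B"))
})

test_that("degenerate series give a missing flag, short series an error", {
  # monotone spread-out series: no template matches at all
  x <- (1:50)^2
  expect_true(is.na(sample_entropy(x, m = 2, r = 0.1)))
  expect_error(sample_entropy(c(1, 2, 3), m = 2, r = 1), "short")
  expect_warning(sample_entropy(rnorm(20), m = 2, r = 1), "unreliable")
})

test_that("mse holds r fixed from the scale-1 series", {
  x <- gen_white_noise(4000, seed = 3)
  cm <- mse(x, taus = c(2, 4, 8))
  expect_equal(cm$r, 0.15 * sd(x))
  se_manual <- as.numeric(sample_entropy(coarse_grain(x, 4), m = 2,
                                         r = 0.15 * sd(x)))
  expect_equal(cm$se[cm$tau == 4], se_manual)
})

test_that("mse of a constant series is zero at every scale", {
  cm <- mse(rep(1, 2000), taus = 2:20)
  expect_true(all(cm$se == 0))
  expect_equal(cm$n_missing, 0L)
  expect_equal(complexity_K(cm)$K, 0)
})

test_that("white-noise entropy falls from small to large scales", {
  x <- gen_white_noise(30000, seed = 12)
  cm <- mse(x, taus = c(2, 100))
  expect_gt(cm$se[1], cm$se[2])
})

test_that("the mse curve is invariant under positive rescaling", {
  x <- gen_white_noise(3000, seed = 5)
  cm1 <- mse(x, taus = c(2, 5, 10))
  cm2 <- mse(37.5 * x, taus = c(2, 5, 10))
  expect_equal(cm1$se, cm2$se, tolerance = 1e-10)
})

test_that("complexity K integrates the curve by trapezoid", {
  flat <- structure(list(tau = 2:100, se = rep(1, 99), m = 2L, r = 0.1,
                         r_frac = 0.15, sd_ref = 1, metric = "chebyshev",
                         n_missing = 0L), class = "mse_curve")
  expect_equal(complexity_K(flat)$K, 98)
  ramp <- flat
  ramp$se <- seq(0, 1, length.out = 99)
  expect_equal(complexity_K(ramp)$K, 49)
  zero <- flat
  zero$se <- rep(0, 99)
  expect_equal(complexity_K(zero)$K, 0)
})

test_that("missing scales are excluded by piecewise integration", {
  cur <- structure(list(tau = c(2:6), se = c(1, 1, NA, 1, 1), m = 2L,
                        r = 0.1, r_frac = 0.15, sd_ref = 1,
                        metric = "chebyshev", n_missing = 1L),
                   class = "mse_curve")
  # two finite runs of width 1 each
  expect_equal(complexity_K(cur)$K, 2)
  expect_equal(complexity_K(cur)$n_missing, 1L)
  all_na <- cur
  all_na$se <- c(NA, NA, NA, NA, 1)
  expect_error(complexity_K(all_na), "finite scales")
})
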