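test_that("find_extrema locates strict extrema and plateau midpoints", {
  ext <- find_extrema(c(0, 1, 0, -1, 0, 1, 0))
  expect_equal(ext$maxima, c(2L, 6L))
  expect_equal(ext$minima, 4L)

  expect_equal(find_extrema(rep(3, 10)),
               list(maxima = integer(0), minima = integer(0)))

  # plateau of length 3 at indices 3:5 -> midpoint 4
  ext <- find_extrema(c(0, 1, 2, 2, 2, 1, 0))
  expect_equal(ext$maxima, 4L)

  # 2 Hz over 10 s: 20 maxima and 20 minima up to boundary effects
  x <- tone(2, 10, 100)
  ext <- find_extrema(x)
  expect_true(abs(length(ext$maxima) - 20) <= 1)
  expect_true(abs(length(ext$minima) - 20) <= 1)

  expect_error(find_extrema(c(1, 2)), "length >= 3")
})

test_that("envelopes hug the extrema and their mean tracks the offset", {
  fps <- 100
  x <- tone(1, 20, fps)
  ext <- find_extrema(x)
  env <- envelopes(x, ext$maxima, ext$minima)
  int <- interior_idx(length(x), 0.1)
  expect_true(all(env$e_max[int] >= env$e_min[int]))
  expect_lt(max(abs(env$m[int])), 0.05)
  # envelope passes through the extrema it interpolates
  expect_equal(env$e_max[ext$maxima], x[ext$maxima], tolerance = 1e-6)
  expect_equal(env$e_min[ext$minima], x[ext$minima], tolerance = 1e-6)

  # constant offset shifts the mean envelope by the same constant
  y <- x + 2.5
  exty <- find_extrema(y)
  envy <- envelopes(y, exty$maxima, exty$minima)
  expect_lt(max(abs(envy$m[int] - 2.5)), 0.05)

  # triangle wave: spline through the peaks stays near the peak amplitude
  tt <- time_grid(20, fps)
  a <- 2
  tri <- a * (2 / pi) * asin(sin(2 * pi * 1 * tt))
  extt <- find_extrema(tri)
  envt <- envelopes(tri, extt$maxima, extt$minima)
  expect_true(all(envt$e_max[int] >= a * 0.9 & envt$e_max[int] <= a * 1.1))

  expect_error(envelopes(x, 1:2, integer(0)), class = "gaithht_not_siftable")
})

test_that("a single sift removes the slow mean and fixes an oscillation", {
  fps <- 50
  x <- tone(1, 20, fps)
  c1 <- sift_once(x)
  expect_lt(sqrt(mean((c1 - x)^2)) / sqrt(mean(x^2)), 0.05)

  # slow trend content drops after one sift
  trend <- 0.8 * time_grid(20, fps) / 20
  y <- x + trend
  c2 <- sift_once(y)
  slow_rms <- function(v, w = 101) {
    sqrt(mean(stats::filter(v, rep(1 / w, w), sides = 2)^2, na.rm = TRUE))
  }
  expect_lt(slow_rms(c2), slow_rms(y))

  expect_error(sift_once(seq(0, 1, length.out = 50)),
               class = "gaithht_not_siftable")
})

test_that("the IMF criterion accepts oscillations and rejects trends/mixtures", {
  expect_true(is_imf(tone(1, 10, 50)))
  expect_false(is_imf(seq(-1, 1, length.out = 100)))
  # unsifted two-tone mixture riding a dominant slow tone: extrema keep the
  # fast rate but zero crossings are lost where the slow tone holds the sum
  # away from zero, so the count criterion fails
  mix <- tone(2, 60, 30) + tone(0.2, 60, 30, amp = 2)
  ext <- find_extrema(mix)
  n_ext <- length(ext$maxima) + length(ext$minima)
  s <- sign(mix)[sign(mix) != 0]
  expect_gt(abs(n_ext - sum(diff(s) != 0)), 1)
  expect_false(is_imf(mix))
  # Cauchy criterion gate
  expect_false(is_imf(tone(1, 10, 50), sd = 0.5, sd_threshold = 0.2))
})

test_that("emd recovers a pure tone as one dominant IMF", {
  fps <- 30
  x <- tone(2, 60, fps)
  dec <- emd(x, fps = fps)
  int <- interior_idx(length(x), 0.05)
  expect_gte(cor(dec$imf_1[int], x[int]), 0.99)
  expect_lt(sqrt(mean(dec$residual^2)), 0.05)
})

test_that("emd separates a classic two-tone mixture", {
  fps <- 30
  fast <- tone(2, 60, fps)
  slow <- tone(0.2, 60, fps)
  dec <- emd(fast + slow, fps = fps)
  expect_gte(n_imfs(dec), 2)
  int <- interior_idx(length(fast), 0.05)
  expect_gte(cor(dec$imf_1[int], fast[int]), 0.95)
  expect_gte(cor(dec$imf_2[int], slow[int]), 0.95)
})

test_that("decomposition is complete and every IMF passes the count criterion", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(256:2048, 1)
    x <- cumsum(rnorm(n)) # random walk: mixes scales
    dec <- emd(x)
    recon <- rowSums(imf_matrix(dec)) + dec$residual
    expect_lt(max(abs(recon - x)), 1e-9)
    for (j in seq_len(n_imfs(dec))) {
      cj <- dec[[paste0("imf_", j)]]
      ext <- find_extrema(cj)
      n_ext <- length(ext$maxima) + length(ext$minima)
      s <- sign(cj)
      zc <- sum(diff(s[s != 0]) != 0)
      expect_lte(abs(n_ext - zc), 1)
    }
  }
})

test_that("decomposition scales linearly with the signal", {
  x <- tone(2, 30, 30) + tone(0.3, 30, 30)
  d1 <- emd(x)
  d2 <- emd(3.5 * x)
  expect_equal(n_imfs(d1), n_imfs(d2))
  expect_equal(3.5 * d1$imf_1, d2$imf_1, tolerance = 1e-8)
  expect_equal(3.5 * d1$residual, d2$residual, tolerance = 1e-8)
})

test_that("degenerate inputs are handled", {
  expect_error(emd(c(1, 2, 3)), "at least 8")
  expect_error(emd(c(1:7, NA)), "non-finite")
  dec <- emd(rep(2, 100))
  expect_equal(n_imfs(dec), 0)
  expect_equal(dec$residual, rep(2, 100))
})

test_that("decomposition agrees with an independent reference on two tones", {
  oracle <- system.file("oracle", "emd_oracle.py", package = "gaithht")
  python <- Sys.which("python")
  x <- tone(2, 60, 30) + tone(0.2, 60, 30)
  f <- tempfile(fileext = ".txt")
  writeLines(format(x, digits = 17), f)
  out <- suppressWarnings(
    try(system2(python, c(shQuote(oracle), shQuote(f)), stdout = TRUE),
        silent = TRUE)
  )
  expect_false(inherits(out, "try-error"))
  ref <- as.matrix(read.csv(textConnection(out), header = FALSE))
  dec <- emd(x, fps = 30)
  expect_lte(abs(ncol(ref) - n_imfs(dec)), 1)
  int <- interior_idx(length(x), 0.05)
  expect_gte(abs(cor(dec$imf_1[int], ref[int, 1])), 0.9)
  expect_gte(abs(cor(dec$imf_2[int], ref[int, 2])), 0.9)
})
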