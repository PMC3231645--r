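test_that("gray-level degradation bins luminance as floor(g/8)", {
  lum <- matrix(c(0, 7, 8, 255, 128, 16), 2, 3)
  lev <- degrade_gray(lum)
  expect_equal(as.vector(lev), c(0, 0, 1, 31, 16, 2))
  # histogram matches a per-pixel binning oracle on a random image
  set.seed(10)
  px <- array(sample(0:255, 12 * 12 * 3, replace = TRUE), c(12, 12, 3))
  img <- leaf_image(px)
  lev2 <- degrade_gray(img)
  lum2 <- luminance(img)
  oracle <- table(factor(floor(pmin(lum2, 255) / 8), levels = 0:31))
  expect_equal(as.vector(table(factor(lev2, levels = 0:31))),
               as.vector(oracle))
})

test_that("GLCM counts match enumeration on closed-form cases", {
  g <- glcm(matrix(c(0, 1, 0, 1), 2, 2), offset = c(1, 0))
  # grid rows: (0,0) and (1,1); horizontal pairs (0,0) and (1,1)
  expect_equal(g$counts[1, 1], 1)
  expect_equal(g$counts[2, 2], 1)
  expect_equal(sum(g$counts), 2)
  # constant grid value k: counts(k,k) = H * (W - 1) for offset (1,0)
  k <- 5
  gc <- glcm(matrix(k, 6, 9), offset = c(1, 0))
  expect_equal(gc$counts[k + 1, k + 1], 6 * 8)
  expect_equal(sum(gc$counts), 6 * 8)
})

test_that("GLCM matches the nested-loop oracle on random masked grids", {
  set.seed(12)
  for (i in 1:20) {
    lev <- matrix(sample(0:31, 64, replace = TRUE), 8, 8)
    if (i %% 2 == 0) lev[matrix(runif(64) < 0.3, 8, 8)] <- NA
    for (off in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 0))) {
      g <- glcm(lev, off)
      expect_identical(g$counts, glcm_bruteforce(lev, off))
    }
  }
})

test_that("reversing the offset transposes the GLCM exactly", {
  set.seed(13)
  lev <- matrix(sample(0:31, 100, replace = TRUE), 10, 10)
  for (off in list(c(1, 0), c(0, 1), c(2, 1))) {
    expect_identical(glcm(lev, -off)$counts, t(glcm(lev, off)$counts))
  }
})

test_that("normalization is idempotent and unit-sum", {
  set.seed(14)
  lev <- matrix(sample(0:31, 144, replace = TRUE), 12, 12)
  g <- glcm(lev, c(1, 0))
  gn <- normalize_glcm(g)
  expect_true(gn$normalized)
  expect_equal(sum(gn$counts), 1, tolerance = 1e-12)
  expect_identical(normalize_glcm(gn), gn)
  g2 <- glcm(matrix(c(0, 0, 1, 1), 2, 2), c(0, 1))
  gn2 <- normalize_glcm(g2)
  expect_equal(sort(gn2$counts[gn2$counts > 0]), c(0.5, 0.5))
})

test_that("texture statistics follow their closed forms", {
  mk <- function(counts) structure(list(counts = counts, offset = c(1, 0),
                                        n_levels = 32, normalized = TRUE),
                                   class = "glcm")
  single <- matrix(0, 32, 32); single[3, 3] <- 1
  expect_equal(texture_energy(mk(single)), 1)
  expect_equal(texture_entropy(mk(single)), 0)
  expect_equal(texture_contrast(mk(single)), 0)
  uni <- matrix(1 / 1024, 32, 32)
  expect_equal(texture_energy(mk(uni)), 1 / 1024, tolerance = 1e-12)
  expect_equal(texture_entropy(mk(uni)), 10, tolerance = 1e-12)
  half <- matrix(0, 32, 32); half[1, 1] <- 0.5; half[2, 2] <- 0.5
  expect_equal(texture_entropy(mk(half)), 1, tolerance = 1e-12)
  offdiag <- matrix(0, 32, 32); offdiag[1, 2] <- 1
  expect_equal(texture_contrast(mk(offdiag)), 1)
  # signed variant drops the minus sign
  expect_equal(texture_entropy(mk(half), signed = TRUE), -1)
})

test_that("texture statistics match weighted-sum oracles on random matrices", {
  set.seed(15)
  for (i in 1:20) {
    p <- matrix(rexp(1024), 32, 32); p <- p / sum(p)
    g <- structure(list(counts = p, offset = c(1, 0), n_levels = 32,
                        normalized = TRUE), class = "glcm")
    expect_equal(texture_energy(g), sum(p^2), tolerance = 1e-12)
    pe <- p[p > 0]
    expect_equal(texture_entropy(g), -sum(pe * log2(pe)), tolerance = 1e-12)
    w <- outer(0:31, 0:31, `-`)^2
    expect_equal(texture_contrast(g), sum(w * p), tolerance = 1e-12)
  }
})

test_that("energy and entropy are antagonistic across random GLCMs", {
  set.seed(16)
  es <- t(replicate(60, {
    conc <- runif(1, 0.5, 30)
    p <- matrix(rgamma(1024, shape = 1 / conc), 32, 32); p <- p / sum(p)
    g <- structure(list(counts = p, offset = c(1, 0), n_levels = 32,
                        normalized = TRUE), class = "glcm")
    c(texture_energy(g), texture_entropy(g))
  }))
  expect_lt(cor(es[, 1], es[, 2], method = "spearman"), 0)
})

test_that("energy respects its theoretical bounds", {
  set.seed(17)
  for (i in 1:20) {
    p <- matrix(rexp(1024), 32, 32); p <- p / sum(p)
    g <- structure(list(counts = p, offset = c(1, 0), n_levels = 32,
                        normalized = TRUE), class = "glcm")
    e <- texture_energy(g)
    expect_gte(e, 1 / 1024)
    expect_lte(e, 1)
  }
})

test_that("degenerate GLCM inputs are rejected", {
  lev <- matrix(NA_integer_, 4, 4)
  expect_error(glcm(lev, c(1, 0)), "no valid")
  expect_error(glcm(matrix(0, 4, 4), c(0, 0)), "nonzero")
  expect_error(glcm(matrix(0, 4, 4), c(4, 0)), "exceeds")
})
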