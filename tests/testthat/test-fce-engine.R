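# Frozen reference values, verified by hand from the membership table before
# being pinned here: B1 = A1.R1 = (0.23, 0.57, 0.20); recomputation gives
# B2 = (0.23, 0.56, 0.21) and B3 = (0.24, 0.56, 0.20) (the printed 0.53,
# 0.26, 0.54 cells are arithmetically inconsistent with the table), and
# V = A.B = (0.2345, 0.5635, 0.202) (printed middle component 0.5575).

table6_R <- function() load_fixture("table6")$membership_matrices

test_that("one-level composition reproduces the reference B1 and fixes B2/B3", {
  R <- table6_R()
  w <- fce_weights()
  expect_equal(one_level(w$A1, R$shape), c(0.23, 0.57, 0.20),
               tolerance = 1e-12)
  expect_equal(one_level(w$A2, R$texture), c(0.23, 0.56, 0.21),
               tolerance = 1e-12)
  expect_equal(one_level(w$A3, R$color), c(0.24, 0.56, 0.20),
               tolerance = 1e-12)
})

test_that("selection and uniform weights behave as matrix identities", {
  R <- table6_R()$shape
  expect_equal(one_level(c(1, 0, 0), R), unname(R[1, ]))
  expect_equal(one_level(rep(1, 3) / 3, R), unname(colMeans(R)))
  B <- rbind(c(0.23, 0.57, 0.20), c(0.23, 0.56, 0.21), c(0.24, 0.56, 0.20))
  expect_equal(two_level(c(1, 0, 0), B), B[1, ])
})

test_that("two-level composition reproduces the reference V components", {
  res <- fce_evaluate(table6_R(), fce_weights())
  expect_equal(round(unname(res$V[1]), 4), 0.2345)
  expect_equal(round(unname(res$V[3]), 3), 0.202)
  # recomputed middle component (printed value is inconsistent); V sums to 1
  expect_equal(round(unname(res$V[2]), 4), 0.5635)
  expect_equal(sum(res$V), 1, tolerance = 1e-12)
})

test_that("normalizing the printed V gives the printed normalized vector", {
  vn <- normalize_v(c(0.2345, 0.5575, 0.202))
  expect_equal(round(vn, 4), c(0.2359, 0.5609, 0.2032))
  # idempotence and a closed-form case
  expect_equal(normalize_v(vn), vn, tolerance = 1e-12)
  expect_equal(normalize_v(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_error(normalize_v(c(0, 0, 0)), "positive")
})

test_that("the decision picks the maximal class and flags ties", {
  res <- fce_evaluate(table6_R(), fce_weights())
  expect_identical(res$label, "B4L")
  expect_identical(decide_class(c(1, 0, 0))$label, "X1L")
  expect_warning(d <- decide_class(c(0.4, 0.4, 0.2)), "tie")
  expect_identical(d$label, "X1L")
})

test_that("unit mass is conserved through both levels", {
  set.seed(20)
  for (i in 1:1000) {
    R_list <- lapply(1:3, function(k) {
      m <- matrix(rexp(9), 3, 3)
      m / rowSums(m)
    })
    w_raw <- lapply(1:4, function(k) { v <- rexp(3); v / sum(v) })
    B <- do.call(rbind, lapply(1:3, function(k)
      one_level(w_raw[[k]], R_list[[k]])))
    V <- two_level(w_raw[[4]], B)
    expect_equal(unname(rowSums(B)), rep(1, 3), tolerance = 1e-6)
    expect_equal(sum(V), 1, tolerance = 1e-6)
  }
})

test_that("compositions agree with naive triple-loop products", {
  set.seed(21)
  for (i in 1:50) {
    A_i <- { v <- rexp(3); v / sum(v) }
    R <- matrix(runif(9), 3, 3); R <- R / rowSums(R)
    naive <- vapply(1:3, function(cc)
      sum(vapply(1:3, function(ff) A_i[ff] * R[ff, cc], numeric(1))),
      numeric(1))
    expect_equal(one_level(A_i, R), naive, tolerance = 1e-12)
    B <- matrix(runif(9), 3, 3)
    A <- { v <- rexp(3); v / sum(v) }
    naive2 <- vapply(1:3, function(cc)
      sum(vapply(1:3, function(ii) A[ii] * B[ii, cc], numeric(1))),
      numeric(1))
    expect_equal(two_level(A, B), naive2, tolerance = 1e-12)
  }
})

test_that("raising a membership entry never lowers the evaluation", {
  set.seed(22)
  R <- matrix(runif(9, 0.1, 0.9), 3, 3)
  A_i <- c(0.3, 0.4, 0.3)
  base <- one_level(A_i, R)
  R2 <- R; R2[2, 1] <- R2[2, 1] + 0.05  # no row renormalization
  expect_gte(one_level(A_i, R2)[1], base[1])
  expect_equal(one_level(A_i, R2)[-1], base[-1])
})

test_that("small weight perturbations do not flip the reference decision", {
  R <- table6_R()
  for (d1 in c(-0.01, 0, 0.01)) for (d2 in c(-0.01, 0, 0.01)) {
    A <- c(0.35 + d1, 0.2 + d2, 0.45 - d1 - d2)
    A <- A / sum(A)
    w <- fce_weights(A = A)
    expect_identical(fce_evaluate(R, w)$label, "B4L")
  }
})

test_that("weight configurations round-trip through YAML and JSON", {
  w <- fce_weights()
  pj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(weights = list(A = w$A, A1 = w$A1, A2 = w$A2,
                                           A3 = w$A3)),
                       pj, auto_unbox = TRUE, digits = NA)
  expect_equal(read_weights(pj), w)
  py <- tempfile(fileext = ".yaml")
  writeLines(c("weights:",
               "  A: [0.35, 0.2, 0.45]",
               "  A1: [0.3, 0.4, 0.3]",
               "  A2: [0.4, 0.3, 0.3]",
               "  A3: [0.3, 0.3, 0.4]"), py)
  expect_equal(read_weights(py), w)
  unlink(c(pj, py))
})

test_that("invalid weights and matrices are rejected", {
  expect_error(fce_weights(A = c(0.5, 0.2, 0.2)), "summing to 1")
  expect_error(fce_weights(A1 = c(-0.1, 0.6, 0.5)), "summing to 1")
  bad <- matrix(c(0.5, 0.2, 0.2, 0.5, 0.2, 0.2, 0.5, 0.2, 0.2), 3, 3)
  expect_error(fce_evaluate(list(bad, bad, bad), fce_weights()), "sum to 1")
  expect_error(one_level(c(0.5, 0.5), matrix(1 / 3, 3, 3)), "match")
})
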