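test_that("random bases are seeded, bounded, and reusable", {
  b <- random_basis(200, 8, seed = 7)
  expect_identical(random_basis(200, 8, seed = 7), b)
  expect_equal(dim(b$A), c(200L, 8L))
  expect_length(b$b, 200)
  expect_true(all(abs(b$A) <= 1) && all(abs(b$b) <= 1))
  b1 <- random_basis(1, 1, seed = 0)
  expect_equal(dim(b1$A), c(1L, 1L))
  expect_length(b1$b, 1)
})

test_that("sigmoid hidden map matches its closed form", {
  b <- random_basis(3, 8, seed = 1)
  # a . x + b = 0 -> 0.5
  b0 <- b
  b0$A[1, ] <- 0
  b0$b[1] <- 0
  expect_equal(hidden_map(rep(0.3, 8), b0)[1], 0.5)
  # a = e1, b = 0, x1 = ln 3 -> 1/(1 + 1/3) = 0.75
  b0$A[2, ] <- c(1, rep(0, 7))
  b0$b[2] <- 0
  expect_equal(hidden_map(c(log(3), rep(0, 7)), b0)[2], 0.75)
  # strictly inside (0, 1) for finite inputs
  set.seed(3)
  h <- hidden_map(matrix(rnorm(50 * 8, sd = 3), 50, 8), b)
  expect_true(all(h > 0 & h < 1))
  expect_error(hidden_map(rep(0, 5), b), "features")
})

test_that("closed-form training equals an independent ridge oracle", {
  # oracle: generic least squares on the augmented system
  #   [H; I/sqrt(C)] beta = [T; 0], solved by QR — an independent route to
  #   argmin ||H beta - T||^2 + ||beta||^2 / C
  ridge_oracle <- function(H, Tm, C) {
    L <- ncol(H)
    qr.solve(rbind(H, diag(1 / sqrt(C), L)),
             rbind(Tm, matrix(0, L, ncol(Tm))))
  }
  set.seed(42)
  for (i in 1:10) {
    N <- sample(5:30, 1)
    L <- sample(2:30, 1)
    K <- sample(2:4, 1)
    H <- matrix(runif(N * L), N, L)
    Tm <- diag(K)[sample(K, N, replace = TRUE), , drop = FALSE]
    C <- 2^sample(1:10, 1)
    expect_lt(max(abs(ridge_solve(H, Tm, C) - ridge_oracle(H, Tm, C))), 1e-8)
    # primal (LxL) and dual (NxN) closed forms agree
    expect_lt(max(abs(ridge_solve(H, Tm, C, form = "primal") -
                        ridge_solve(H, Tm, C, form = "dual"))), 1e-8)
  }
  # identity limit of ridge: H = I, C large -> beta -> T
  Tm <- diag(6)
  expect_equal(ridge_solve(diag(6), Tm, C = 1e10), Tm, tolerance = 1e-8)
})

test_that("end-to-end training memorizes separated clusters and is deterministic", {
  d <- cluster_data(n = 20, spread = 0.01)
  basis <- random_basis(200, 8, seed = 2)
  m1 <- elm_train(d$x, d$y, basis, C = 2^7)
  m2 <- elm_train(d$x, d$y, basis, C = 2^7)
  expect_identical(m1$beta, m2$beta)  # same basis + data -> same weights
  expect_equal(mean(predict(m1, d$x) == d$y), 1)  # 100% resubstitution
  # two far-apart single-sample classes: queries at the training points
  x2 <- rbind(rep(0.1, 8), rep(0.9, 8))
  m3 <- elm_train(rbind(x2, x2), c(1, 2, 1, 2), random_basis(20, 8, 1), C = 2^7)
  expect_equal(predict(m3, x2), c(1, 2))
  sc <- predict(m3, x2, type = "score")
  expect_equal(dim(sc), c(2L, 2L))
  expect_error(elm_train(d$x, rep(9, nrow(d$x)), basis, C = 2^7,
                         class_labels = 1:6), "outside")
})

test_that("argmax ties break toward the earliest class label", {
  basis <- random_basis(4, 8, seed = 1)
  model <- structure(list(basis = basis,
                          beta = matrix(1, 4, 3),  # all classes score equally
                          C = 1, class_labels = c(2L, 5L, 6L), norm = NULL),
                     class = "elm_model")
  expect_equal(predict(model, rep(0.5, 8)), 2L)
})

test_that("accuracy is flat across the recommended C range and rises with L", {
  d <- cluster_data(n = 10, spread = 0.05, seed = 8)
  set.seed(9)
  test_x <- d$x + rnorm(length(d$x), sd = 0.05)
  basis <- random_basis(200, 8, seed = 3)
  acc_c <- vapply(5:11, function(p) {
    m <- elm_train(d$x, d$y, basis, C = 2^p)
    mean(predict(m, test_x) == d$y)
  }, numeric(1))
  expect_lt(max(acc_c) - min(acc_c), 0.1)  # plateau over C = 2^5..2^11
  # median accuracy over basis seeds is non-decreasing in L up to plateau
  med_acc <- vapply(c(10, 50, 200), function(L) {
    median(vapply(1:7, function(s) {
      m <- elm_train(d$x, d$y, random_basis(L, 8, seed = s), C = 2^7)
      mean(predict(m, test_x) == d$y)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_acc) >= 0))
})

test_that("models round-trip through their JSON serialization", {
  d <- cluster_data(n = 5, spread = 0.02)
  norm <- fit_normalization(d$x)
  model <- elm_train(apply_normalization(d$x, norm), d$y,
                     random_basis(30, 8, seed = 6), C = 2^7, norm = norm)
  path <- withr::local_tempfile(fileext = ".json")
  write_elm_model(model, path)
  back <- read_elm_model(path)
  expect_identical(back$basis$L, model$basis$L)
  expect_identical(back$basis$seed, model$basis$seed)
  expect_equal(back$C, model$C)
  expect_equal(back$class_labels, model$class_labels)
  expect_lt(max(abs(back$beta - model$beta)), 1e-12)
  expect_lt(max(abs(back$basis$A - model$basis$A)), 1e-12)
  expect_equal(back$norm$min, model$norm$min, tolerance = 1e-12)
  # restored model predicts identically
  xn <- apply_normalization(d$x, norm)
  expect_identical(predict(back, xn), predict(model, xn))
})

test_that("training 900 x 8 features with L = 200 is fast", {
  set.seed(10)
  x <- matrix(runif(900 * 8), 900, 8)
  y <- rep(1:6, each = 150)
  t0 <- proc.time()[["elapsed"]]
  elm_train(x, y, random_basis(200, 8, seed = 1), C = 2^7)
  expect_lt(proc.time()[["elapsed"]] - t0, 3)
})
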