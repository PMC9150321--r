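test_that("the initial stringency threshold is the interpolated order-statistic quantile", {
  sc <- score_table(tumor = rep(0.7, 20), normal = rep(0.4, 20))
  expect_equal(initial_stringency(sc), 0.3)
  d <- 0.01 * (1:100)
  sc2 <- score_table(tumor = d, normal = rep(0, 100))
  # type-7 oracle: h = (n - 1) q + 1 = 90.1 -> x[90] + 0.1 (x[91] - x[90])
  expect_equal(initial_stringency(sc2, 0.9), 0.90 + 0.1 * 0.01)
  expect_equal(initial_stringency(sc2, 1.0), 1.0)
})

test_that("an edgeless graph leaves the argmax labels untouched and stops at once", {
  n <- 12
  set.seed(4)
  p_t <- runif(n)
  probs <- cbind(Normal = 1 - p_t, Tumor = p_t)
  sc <- score_table(tumor = p_t, normal = 1 - p_t)
  g <- manual_graph(matrix(0, n, n))
  res <- propagate_labels(probs, sc, g)
  expect_equal(res$n_iterations, 1L)
  expect_identical(as.character(res$labels),
                   c("Normal", "Tumor")[max.col(probs, ties.method = "first")])
  expect_equal(res$probabilities, probs, ignore_attr = TRUE)
})

test_that("cliques adopt the label of their confident seed", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 0.8; W[6:10, 6:10] <- 0.8
  diag(W) <- 0
  g <- manual_graph(W)
  probs <- matrix(0.5, 10, 2, dimnames = list(NULL, c("Normal", "Tumor")))
  probs[1, ] <- c(0.05, 0.95)   # tumor seed in clique 1
  probs[6, ] <- c(0.95, 0.05)   # normal seed in clique 2
  sc <- score_table(tumor = c(1, rep(0.5, 4), 0, rep(0.5, 4)),
                    normal = c(0, rep(0.5, 4), 1, rep(0.5, 4)))
  res <- propagate_labels(probs, sc, g, lambda = 0.25)
  expect_identical(as.character(res$labels),
                   rep(c("Tumor", "Normal"), each = 5))
})

test_that("one propagation step equals the dense matrix-product oracle", {
  set.seed(55)
  for (rep in 1:5) {
    n <- 5
    W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
    p_t <- runif(n)
    probs <- cbind(Normal = 1 - p_t, Tumor = p_t)
    ts <- runif(n); ns <- runif(n)
    sc <- score_table(tumor = ts, normal = ns)
    g <- manual_graph(W)
    # change_tol > 1 forces exactly one update before termination
    res <- propagate_labels(probs, sc, g, q0 = 0.7, lambda = 0.3,
                            change_tol = 1.01)
    d <- ts - ns
    N0 <- quantile(d, 0.7, type = 7, names = FALSE)
    masked <- probs
    masked[abs(d) < N0, ] <- 0
    prop <- W %*% masked
    rs <- rowSums(prop)
    for (i in 1:n) {
      if (rs[i] > 0) prop[i, ] <- prop[i, ] / rs[i] else prop[i, ] <- probs[i, ]
    }
    expect_equal(unname(res$probabilities), unname(prop), tolerance = 1e-12)
    expect_equal(res$N0, N0)
  }
})

test_that("the threshold sequence decays strictly and lambda is validated", {
  set.seed(10)
  n <- 30
  W <- matrix(runif(n * n) < 0.2, n, n) * 0.5
  W <- (W + t(W)) / 2; diag(W) <- 0
  p_t <- runif(n)
  probs <- cbind(1 - p_t, p_t)
  sc <- score_table(tumor = runif(n), normal = runif(n))
  g <- manual_graph(W)
  res <- suppressWarnings(
    propagate_labels(probs, sc, g, lambda = 0.4, max_iter = 8,
                     change_tol = 0))
  expect_true(all(diff(res$thresholds) < 0))
  expect_equal(res$thresholds, res$N0 * exp(-0.4 * (seq_along(res$thresholds) - 1)))
  expect_error(propagate_labels(probs, sc, g, lambda = 0),
               "configuration error")
})

test_that("propagation terminates with valid probabilities on random graphs", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(20:50, 1)
    W <- matrix(runif(n * n) < 0.15, n, n) * runif(n * n)
    W <- (W + t(W)) / 2; diag(W) <- 0
    p_t <- runif(n)
    probs <- cbind(Normal = 1 - p_t, Tumor = p_t)
    sc <- score_table(tumor = runif(n), normal = runif(n))
    g <- manual_graph(W)
    res <- withCallingHandlers(
      propagate_labels(probs, sc, g, max_iter = 30),
      warning = function(w) invokeRestart("muffleWarning"))
    expect_true(res$converged || res$n_iterations == 30)
    expect_true(all(res$probabilities >= 0 & res$probabilities <= 1 + 1e-12))
    expect_equal(unname(rowSums(res$probabilities)), rep(1, n),
                 tolerance = 1e-9)
    # static masking statistic + decaying threshold => unmasked set only grows
    d <- sc$tumor_score - sc$normal_score
    masks <- lapply(res$thresholds, function(Nt) abs(d) >= Nt)
    if (length(masks) > 1) {
      for (i in seq_len(length(masks) - 1)) {
        expect_true(all(!masks[[i]] | masks[[i + 1]]))
      }
    }
  }
})
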