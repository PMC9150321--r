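# Independent scalar oracle for the overestimated-variance t-test: plain
# per-gene arithmetic, no vectorization shared with the implementation.
de_oracle_gene <- function(x_up, x_dn) {
  n1 <- length(x_up); n2 <- length(x_dn)
  m1 <- sum(x_up) / n1; m2 <- sum(x_dn) / n2
  v_up <- sum((x_up - m1)^2) / (n1 - 1)
  v_dn <- sum((x_dn - m2)^2) / (n2 - 1)
  a <- v_up / n1
  b <- v_dn / n1  # shared (up-group) denominator inflates the SE
  tt <- (m1 - m2) / sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  list(t = tt, p = 2 * pt(-abs(tt), df), log2fc = m1 - m2)
}

make_de_dataset <- function(m_up, m_dn, genes) {
  m <- rbind(m_up, m_dn)
  dimnames(m) <- list(sprintf("c%02d", seq_len(nrow(m))), genes)
  expression_dataset(m, data.frame(
    cell_type = rep(c("Tumor", "Normal"), c(nrow(m_up), nrow(m_dn))),
    stringsAsFactors = FALSE))
}

test_that("identical per-gene distributions give t = 0, log2fc = 0, p = 1", {
  set.seed(1)
  block <- matrix(runif(3 * 4, 0, 5), 3, 4)
  d <- make_de_dataset(block, block, paste0("g", 1:4))
  res <- differential_expression(d, "Tumor", "Normal", "cell_type")
  expect_equal(res$t_statistic, rep(0, 4))
  expect_equal(res$log2fc, rep(0, 4))
  expect_equal(res$p_value, rep(1, 4))
  expect_equal(res$p_adj, rep(1, 4))
})

test_that("t and p match the scalar formula oracle on 50 random instances", {
  set.seed(99)
  for (i in 1:50) {
    n1 <- sample(3:6, 1); n2 <- sample(3:8, 1); g <- 4
    m_up <- matrix(runif(n1 * g, 0, 6), n1, g)
    m_dn <- matrix(runif(n2 * g, 0, 6), n2, g)
    d <- make_de_dataset(m_up, m_dn, paste0("g", seq_len(g)))
    res <- differential_expression(d, "Tumor", "Normal", "cell_type")
    for (j in seq_len(g)) {
      o <- de_oracle_gene(m_up[, j], m_dn[, j])
      expect_equal(res$t_statistic[j], o$t, tolerance = 1e-10)
      expect_equal(res$p_value[j], o$p, tolerance = 1e-10)
      expect_equal(res$log2fc[j], o$log2fc, tolerance = 1e-10)
    }
    expect_true(all(res$p_adj >= res$p_value - 1e-12))
  }
})

test_that("a clean on/off gene gets log2fc equal to its level and ranks first", {
  set.seed(5)
  m_up <- cbind(rep(5, 4), matrix(runif(4 * 3, 0, 2), 4, 3))
  m_dn <- cbind(rep(0, 6), matrix(runif(6 * 3, 0, 2), 6, 3))
  d <- make_de_dataset(m_up, m_dn, paste0("g", 1:4))
  res <- differential_expression(d, "Tumor", "Normal", "cell_type")
  expect_equal(res$log2fc[1], 5)
  expect_equal(which.max(res$log2fc), 1L)
})

test_that("class errors are informative", {
  d <- rand_dataset(seed = 11)
  expect_error(differential_expression(d, "Missing", "Normal", "cell_type"),
               "absent")
  d1 <- d
  d1$annotations$cell_type <- c("Tumor", rep("Normal", nrow(d$matrix) - 1))
  expect_error(differential_expression(d1, "Tumor", "Normal", "cell_type"),
               "insufficient cells")
  expect_error(differential_expression(d, "Tumor", "Normal", "nope"),
               "not found")
})

fake_de <- function(genes, log2fc, p_adj, comparison = c(up = "T", down = "N")) {
  d <- data.frame(gene = genes, log2fc = log2fc, t_statistic = 0,
                  p_value = p_adj, p_adj = p_adj, stringsAsFactors = FALSE)
  attr(d, "comparison") <- comparison
  class(d) <- c("de_result", "data.frame")
  d
}

test_that("averaging uses only datasets passing the p_adj filter", {
  d1 <- fake_de(c("a", "b", "c"), c(3, 1, 2), c(0.01, 0.2, 0.05))
  d2 <- fake_de(c("a", "b", "c"), c(1, 1, 4), c(0.05, 0.2, 0.2))
  out <- average_and_rank(list(d1, d2), n_top = 10)
  # b fails everywhere -> dropped; c passes only in d1 -> average over d1 only
  expect_false("b" %in% out$gene)
  expect_equal(out$avg_log2fc[out$gene == "a"], 2)   # (3 + 1) / 2
  expect_equal(out$avg_log2fc[out$gene == "c"], 2)   # d1 only
  expect_equal(out$n_datasets[out$gene == "a"], 2L)
  # tie between a and c at 2.0 broken lexicographically
  expect_identical(out$gene, c("a", "c"))
})

test_that("ranking matches an independent sort oracle and respects n_top", {
  set.seed(21)
  genes <- paste0("g", sprintf("%02d", 1:10))
  fc <- round(rnorm(10), 1)  # duplicates likely -> exercises tie-break
  d1 <- fake_de(genes, fc, rep(0.01, 10))
  out <- average_and_rank(list(d1), n_top = 6)
  oracle <- genes[order(-fc, genes)][1:6]
  expect_identical(out$gene, oracle)
  # fewer surviving genes than n_top returns them all
  d2 <- fake_de(genes, fc, c(rep(0.01, 3), rep(0.5, 7)))
  expect_equal(nrow(average_and_rank(list(d2), n_top = 300)), 3)
})

test_that("averaging is invariant to dataset order", {
  set.seed(31)
  mk <- function(s) fake_de(paste0("g", 1:20), rnorm(20), runif(20, 0, 0.3))
  ds <- lapply(1:3, mk)
  a <- average_and_rank(ds, n_top = 15)
  b <- average_and_rank(rev(ds), n_top = 15)
  expect_identical(a, b)
})

test_that("signature integration takes intersections up and unions down", {
  l1 <- c("A", "B", "C"); l2 <- c("B", "C", "D")
  expect_identical(integrate_signatures(list(l1, l2), "up"), c("B", "C"))
  expect_identical(integrate_signatures(list(l1, l2), "down"),
                   c("A", "B", "C", "D"))
  expect_identical(integrate_signatures(list(l1), "up"), sort(l1))
  expect_identical(integrate_signatures(list(l1), "down"), sort(l1))
  # subset / superset properties on random lists
  set.seed(8)
  lists <- replicate(4, sample(paste0("g", 1:30), 12), simplify = FALSE)
  up <- integrate_signatures(lists, "up")
  dn <- integrate_signatures(lists, "down")
  for (l in lists) {
    expect_true(all(up %in% l))
    expect_true(all(l %in% dn))
  }
})

test_that("empty consolidation warns and returns an empty list", {
  d1 <- fake_de("a", 1, 0.5)
  expect_warning(out <- average_and_rank(list(d1)), "empty")
  expect_equal(nrow(out), 0)
  expect_warning(integrate_signatures(list(c("A"), c("B")), "up"), "empty")
})
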