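# Independent re-computation of the whole profile pipeline with plain
# loops: filter, log-normalize, reference-center, clip, truncated moving
# average per chromosome, per-cell median re-centering.
cnv_oracle <- function(counts, positions, ref_ids, window, cutoff) {
  pos <- positions[positions$gene %in% colnames(counts), , drop = FALSE]
  counts <- counts[, pos$gene, drop = FALSE]
  keep <- colMeans(counts) >= cutoff
  pos <- pos[keep, , drop = FALSE]
  counts <- counts[, keep, drop = FALSE]
  totals <- rowSums(counts); totals[totals == 0] <- 1
  ln <- log2(1 + 1e4 * counts / totals)
  ref <- colMeans(ln[rownames(counts) %in% ref_ids, , drop = FALSE])
  rel <- sweep(ln, 2, ref)
  rel[rel > 3] <- 3; rel[rel < -3] <- -3
  half <- (window - 1) / 2
  sm <- rel
  for (j in seq_len(ncol(rel))) {
    same <- which(pos$chromosome == pos$chromosome[j])
    win <- same[same >= j - half & same <= j + half]
    for (i in seq_len(nrow(rel))) sm[i, j] <- mean(rel[i, win])
  }
  sm - apply(sm, 1, median)
}

test_that("profiles match the sliding-window oracle and expose planted gains", {
  co <- tiny_cohort(seed = 14, n_datasets = 1, n_cells = 120, n_genes = 400,
                    n_planted_up = 20, n_planted_down = 20,
                    cnv = FALSE, effect_size = 1)
  d <- co$datasets[[1]]
  # plant a clean 2x gain over a contiguous block of chr1 in tumor cells
  tum <- truth_of(d) == "Tumor"
  block <- co$truth$positions$gene[co$truth$positions$chromosome == "chr1"][5:35]
  d$counts[tum, block] <- d$counts[tum, block] * 2
  ref <- d$cell_ids[!tum]
  prof <- suppressWarnings(
    infer_cnv_profile(d, co$truth$positions, ref, window = 11, cutoff = 0.1))
  oracle <- cnv_oracle(d$counts, co$truth$positions, ref, 11, 0.1)
  expect_equal(prof$matrix, oracle, tolerance = 1e-12)
  in_block <- colnames(prof$matrix) %in% block
  expect_gt(mean(prof$matrix[tum, in_block]),
            mean(prof$matrix[!tum, in_block]) + 0.1)
})

test_that("cells from the reference distribution give a structureless near-zero profile", {
  # tumor cells are drawn from the reference distribution here, so the
  # smoothed profile should carry no signal: per-gene reference means stay
  # within +-0.05 (the centering invariant) and typical deviations stay
  # within +-0.1; extreme single entries of the 101-gene moving average
  # over ~10^6 count draws legitimately exceed that band
  co <- tiny_cohort(seed = 15, n_datasets = 1, n_cells = 150,
                    n_genes = 6000, n_planted_up = 0, n_planted_down = 0,
                    cnv = FALSE, effect_size = 0)
  d <- co$datasets[[1]]
  ref <- d$cell_ids[truth_of(d) == "Normal"]
  prof <- infer_cnv_profile(d, co$truth$positions, ref, window = 101)
  x <- prof$matrix
  expect_lt(max(abs(colMeans(x[rownames(x) %in% ref, ]))), 0.05)
  expect_lt(mean(abs(x)), 0.1)
  tum <- truth_of(d) == "Tumor"
  # no planted difference -> tumor and reference profiles indistinguishable
  expect_lt(abs(mean(x[tum, ]) - mean(x[!tum, ])), 0.02)
})

test_that("low-expression genes are dropped before smoothing", {
  co <- tiny_cohort(seed = 16, n_datasets = 1, n_cells = 100, n_genes = 300,
                    n_planted_up = 10, n_planted_down = 10, cnv = FALSE)
  d <- co$datasets[[1]]
  g_low <- d$gene_symbols[42]
  d$counts[, g_low] <- 0
  d$counts[1:3, g_low] <- 1  # mean 0.03 < 0.1
  prof <- suppressWarnings(
    infer_cnv_profile(d, co$truth$positions,
                      d$cell_ids[truth_of(d) == "Normal"], window = 11))
  expect_false(g_low %in% colnames(prof$matrix))
})

test_that("profiles are invariant to the input order of gene columns", {
  co <- tiny_cohort(seed = 17, n_datasets = 1, n_cells = 80, n_genes = 200,
                    n_planted_up = 10, n_planted_down = 10)
  d <- co$datasets[[1]]
  ref <- d$cell_ids[truth_of(d) == "Normal"]
  p1 <- suppressWarnings(
    infer_cnv_profile(d, co$truth$positions, ref, window = 11))
  perm <- sample(ncol(d$matrix))
  d2 <- d
  d2$matrix <- d$matrix[, perm]
  d2$counts <- d$counts[, perm]
  d2$gene_symbols <- d$gene_symbols[perm]
  p2 <- suppressWarnings(
    infer_cnv_profile(d2, co$truth$positions, ref, window = 11))
  expect_equal(p1$matrix, p2$matrix)
})

test_that("cnv_summary reduces profiles to per-cell mean and variance", {
  zero <- structure(list(
    matrix = matrix(0, 3, 5, dimnames = list(paste0("c", 1:3), paste0("g", 1:5))),
    gene_order = NULL, window = 1L, reference_cells = character(0)),
    class = "cnv_profile")
  s <- cnv_summary(zero)
  expect_equal(s$cnv_mean, rep(0, 3))
  expect_equal(s$cnv_var, rep(0, 3))
  toy <- zero
  toy$matrix <- matrix(c(1, 2, 3, 4), 1, 4,
                       dimnames = list("c1", paste0("g", 1:4)))
  s2 <- cnv_summary(toy)
  expect_equal(s2$cnv_mean, 2.5)
  expect_equal(s2$cnv_var, sum((c(1, 2, 3, 4) - 2.5)^2) / 3)
})

test_that("tumor cells with planted gains show higher CNV mean and variance", {
  co <- tiny_cohort(seed = 18, n_datasets = 1, n_cells = 250, n_genes = 600,
                    n_planted_up = 0, n_planted_down = 0, effect_size = 0,
                    cnv = TRUE)
  d <- co$datasets[[1]]
  tum <- truth_of(d) == "Tumor"
  prof <- suppressWarnings(
    infer_cnv_profile(d, co$truth$positions, d$cell_ids[!tum], window = 51))
  s <- cnv_summary(prof)
  expect_gt(median(s$cnv_mean[tum]), median(s$cnv_mean[!tum]))
  expect_gt(median(s$cnv_var[tum]), median(s$cnv_var[!tum]))
})

test_that("proofreading flips exactly the high-confidence discordant cells", {
  co <- tiny_cohort(seed = 19, n_datasets = 1, n_cells = 250, n_genes = 600,
                    n_planted_up = 0, n_planted_down = 0, effect_size = 0,
                    cnv = TRUE)
  d <- co$datasets[[1]]
  truth <- truth_of(d)
  prof <- suppressWarnings(
    infer_cnv_profile(d, co$truth$positions,
                      d$cell_ids[truth == "Normal"], window = 51))
  # concordant labels: nothing flips
  clean <- cnv_proofread(prof, truth, flip_probability = 0.9)
  expect_equal(nrow(clean$flips), 0)
  expect_identical(as.character(clean$labels), truth)
  # plant discordant labels; flips must follow the probability rule exactly
  noisy <- plant_label_noise(truth, 0.06, seed = 5)
  res <- cnv_proofread(prof, noisy$labels, flip_probability = 0.9)
  p_opp <- ifelse(noisy$labels == "Tumor", res$probabilities[, "Normal"],
                  res$probabilities[, "Tumor"])
  should_flip <- which(p_opp > 0.9)
  expect_setequal(res$flips$cell_id, d$cell_ids[should_flip])
  expect_true(all(res$flips$probability > 0.9))
  # cells below the confidence cut keep their (pseudo) label
  kept <- setdiff(seq_along(truth), should_flip)
  expect_identical(as.character(res$labels)[kept], noisy$labels[kept])
  expect_lte(nrow(res$flips), length(noisy$flipped))
})

test_that("single-class pseudo-labels leave labels unchanged with a warning", {
  co <- tiny_cohort(seed = 20, n_datasets = 1, n_cells = 100, n_genes = 200,
                    n_planted_up = 5, n_planted_down = 5)
  d <- co$datasets[[1]]
  prof <- suppressWarnings(
    infer_cnv_profile(d, co$truth$positions, d$cell_ids[1:20], window = 11))
  expect_warning(res <- cnv_proofread(prof, rep("Normal", 100)),
                 "single-class")
  expect_identical(as.character(res$labels), rep("Normal", 100))
})

test_that("CNV-only classifiers generalize only to cohorts sharing the CNV architecture", {
  seg_a <- list(list(chromosome = "chr1", start = 1, n_genes = 60, fold = 2))
  seg_b <- list(list(chromosome = "chr4", start = 1, n_genes = 60, fold = 2))
  mk <- function(seed, segs) {
    co <- simulate_cohort(cohort_spec(
      n_datasets = 1, n_cells = 200, n_genes = 600, n_planted_up = 0,
      n_planted_down = 0, effect_size = 0, cnv_segments = segs, seed = seed))
    d <- co$datasets[[1]]
    prof <- suppressWarnings(
      infer_cnv_profile(d, co$truth$positions,
                        d$cell_ids[truth_of(d) == "Normal"], window = 51))
    list(profile = prof, labels = truth_of(d))
  }
  a1 <- mk(31, seg_a); a2 <- mk(32, seg_a); b <- mk(33, seg_b)
  acc <- train_cnv_baseline(list(a1 = a1$profile, a2 = a2$profile,
                                 b = b$profile),
                            list(a1$labels, a2$labels, b$labels), seed = 1)
  expect_gt(acc["a1", "a1"], 0.9)
  expect_gt(acc["b", "b"], 0.9)
  expect_gt(acc["a1", "a2"], 0.9)   # shared architecture transfers
  expect_lt(acc["a1", "b"], 0.75)   # disjoint segments do not
  expect_lt(acc["b", "a1"], 0.75)
  expect_error(train_cnv_baseline(list(a1$profile), list(a1$labels)),
               "2 cohorts are required")
})

test_that("CNV inference validates its inputs", {
  co <- tiny_cohort(seed = 21, n_datasets = 1, n_cells = 50, n_genes = 100,
                    n_planted_up = 5, n_planted_down = 5)
  d <- co$datasets[[1]]
  expect_error(infer_cnv_profile(d, co$truth$positions, d$cell_ids[1:5]),
               "at least 10 reference cells")
  expect_error(infer_cnv_profile(d, co$truth$positions, d$cell_ids[1:20],
                                 window = 10), "odd")
  d$counts <- NULL
  expect_error(infer_cnv_profile(d, co$truth$positions, d$cell_ids[1:20]),
               "counts")
})
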