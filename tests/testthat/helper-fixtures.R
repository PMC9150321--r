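# Fixtures are generated in code: small synthetic cohorts and random
# expression datasets used across the test files.

tiny_cohort <- function(seed = 1, n_datasets = 3, n_cells = 300,
                        n_genes = 800, n_planted_up = 60,
                        n_planted_down = 60, cnv = TRUE,
                        effect_size = 1.5, ...) {
  seg_len <- min(60L, max(5L, floor(0.8 * n_genes / 10)))
  segs <- if (isTRUE(cnv))
    list(list(chromosome = "chr2", start = 1, n_genes = seg_len, fold = 2))
  else NULL
  simulate_cohort(cohort_spec(
    n_datasets = n_datasets, n_cells = n_cells, n_genes = n_genes,
    n_planted_up = n_planted_up, n_planted_down = n_planted_down,
    cnv_segments = segs, effect_size = effect_size, seed = seed, ...))
}

truth_of <- function(dataset) {
  ifelse(dataset$annotations$cell_type == "Tumor", "Tumor", "Normal")
}

# random nonnegative expression dataset (not cohort-structured)
rand_dataset <- function(seed = 1, n_cells = 30, n_genes = 50,
                         counts = FALSE, name = "rand") {
  set.seed(seed)
  m <- matrix(round(abs(rnorm(n_cells * n_genes, 2, 1)), 3),
              nrow = n_cells,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("g%03d", seq_len(n_genes))))
  cnt <- if (counts) {
    k <- matrix(rpois(n_cells * n_genes, 5), nrow = n_cells,
                dimnames = dimnames(m))
    storage.mode(k) <- "double"
    k
  } else NULL
  expression_dataset(
    m, data.frame(cell_type = sample(c("Tumor", "Normal"), n_cells,
                                     replace = TRUE),
                  stringsAsFactors = FALSE),
    counts = cnt, dataset_name = name)
}

# a cell_graph with explicitly given dense connectivities
manual_graph <- function(W, ids = NULL) {
  n <- nrow(W)
  if (is.null(ids)) ids <- sprintf("c%02d", seq_len(n))
  Ws <- methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix")
  dimnames(Ws) <- list(ids, ids)
  structure(list(connectivities = Ws, k = NA_integer_,
                 n_components_used = NA_integer_, cell_ids = ids),
            class = "cell_graph")
}

# minimal score table for propagation tests
score_table <- function(tumor, normal) {
  structure(data.frame(cell_id = sprintf("c%02d", seq_along(tumor)),
                       tumor_score = tumor, normal_score = normal,
                       stringsAsFactors = FALSE),
            class = c("signature_scores", "data.frame"))
}
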