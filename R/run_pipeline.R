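# End-to-end orchestration with file artifacts, for script/CLI use. The
# programmatic interface ([tumor_classifier()] / predict) is the primary
# surface; this wrapper adds file IO, a manifest, and stable per-stage
# seeding so runs are reproducible from a single configuration.

#' Run the full pipeline from a configuration
#'
#' Stages: read training/test datasets (h5ad paths or
#' [expression_dataset()] objects) — derive signatures (skipped when a GMT
#' is supplied) — score and train — predict on each test dataset (with
#' propagation, plus CNV proofreading when a gene-position table is given).
#' Artifacts written to `out_dir`: `signatures.gmt`, `model.json`, per-test
#' `scores_<name>.csv` and `labels_<name>.csv`, and `manifest.json`
#' (configuration, seed, package version).
#'
#' @param config A named list (or path to a YAML/JSON file) with fields:
#'   `train` (paths/objects; optional when `signatures_gmt` given — then
#'   the classifier still needs `train` for score training), `test`
#'   (paths/objects), `label_column`, `tumor_label` (default `"Tumor"`),
#'   `signatures_gmt` (optional path), `positions` (optional TSV path;
#'   enables CNV proofreading), `out_dir`, `seed` (default 1), plus any of
#'   the tuning fields `n_top`, `p_adj_threshold`, `max_rank_fraction`,
#'   `q0`, `lambda`, `flip_probability`.
#' @return Invisibly, a list with the fitted `model`, per-test prediction
#'   tables, and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$label_column),
            !is.null(config$out_dir))
  get <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  seed <- get("seed", 1)
  tumor_label <- get("tumor_label", "Tumor")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  load_ds <- function(x) {
    if (inherits(x, "expression_dataset")) return(x)
    read_h5ad(x, label_columns = config$label_column)
  }
  train <- lapply(get("train", list()), load_ds)
  test <- lapply(get("test", list()), load_ds)
  signatures <- NULL
  if (!is.null(config$signatures_gmt)) {
    sigs <- read_gmt(config$signatures_gmt)
    if (!all(c("tumor", "normal") %in% names(sigs)))
      stop("signatures GMT must contain sets named 'tumor' and 'normal'",
           call. = FALSE)
    signatures <- list(
      tumor = sigs$tumor,
      normal = gene_signature("normal", sigs$normal$genes, "down_in_class"))
  }
  if (!length(train))
    stop("`train` datasets are required to fit the score classifier",
         call. = FALSE)
  set.seed(seed)  # stages draw no randomness, but pin the stream anyway
  model <- tumor_classifier(
    train, config$label_column, tumor_label = tumor_label,
    signatures = signatures,
    n_top = get("n_top", 300),
    p_adj_threshold = get("p_adj_threshold", 0.1),
    max_rank_fraction = get("max_rank_fraction", 0.05))
  write_gmt(model$signatures, file.path(out_dir, "signatures.gmt"))
  write_score_classifier(model$classifier, file.path(out_dir, "model.json"))
  positions <- NULL
  if (!is.null(config$positions))
    positions <- if (is.character(config$positions))
      read_gene_positions(config$positions) else config$positions
  predictions <- list()
  for (d in test) {
    pred <- predict(model, d, propagate = TRUE,
                    cnv_correct = !is.null(positions) && !is.null(d$counts),
                    positions = positions,
                    q0 = get("q0", 0.9), lambda = get("lambda", 0.25),
                    flip_probability = get("flip_probability", 0.9))
    nm <- d$dataset_name
    write.csv(pred[, c("cell_id", "tumor_score", "normal_score")],
              file.path(out_dir, paste0("scores_", nm, ".csv")),
              row.names = FALSE)
    write.csv(pred, file.path(out_dir, paste0("labels_", nm, ".csv")),
              row.names = FALSE)
    predictions[[nm]] <- pred
  }
  manifest <- list(
    package = "sctumor",
    version = as.character(utils::packageVersion("sctumor")),
    seed = seed, label_column = config$label_column,
    tumor_label = tumor_label,
    train = vapply(train, function(d) d$dataset_name, character(1)),
    test = vapply(test, function(d) d$dataset_name, character(1)),
    signatures_provided = !is.null(signatures),
    n_tumor_signature = length(model$signatures$tumor),
    n_normal_signature = length(model$signatures$normal))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = model, predictions = predictions,
                 out_dir = out_dir))
}
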