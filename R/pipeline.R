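# Pipeline orchestration: configuration, subcommands, provenance.

#' Pipeline configuration
#'
#' Collects the paths and parameters the pipeline stages need. Defaults match
#' the published analysis: subgraph-centrality threshold 1e23 (strict), top
#' 10 targets, negative-to-positive ratio 1.5, weak-binder threshold 10 uM,
#' forest with 150 trees and 100 split features. One master `seed` fans out
#' to stage-specific seeds via [derive_seed()], so every stage is
#' independently reproducible.
#'
#' @param graph,fasta,ligands,interactions Input paths.
#' @param out_dir Output directory for artifacts.
#' @param sc_min Strict subgraph-centrality threshold (default 1e23).
#' @param top_k Shortlist length (default 10).
#' @param ratio Negative-to-positive ratio (default 1.5).
#' @param threshold_um Weak-binder bioactivity threshold in uM (default 10).
#' @param n_trees,max_features Forest hyperparameters (defaults 150, 100).
#' @param min_score STRING combined-score cutoff (default 0 = keep all).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(graph = NULL, fasta = NULL, ligands = NULL,
                            interactions = NULL, out_dir = ".",
                            sc_min = 1e23, top_k = 10, ratio = 1.5,
                            threshold_um = 10, n_trees = 150,
                            max_features = 100, min_score = 0, seed = 1L) {
  structure(list(
    graph = graph, fasta = fasta, ligands = ligands,
    interactions = interactions, out_dir = out_dir,
    sc_min = sc_min, top_k = top_k, ratio = ratio,
    threshold_um = threshold_um, n_trees = n_trees,
    max_features = max_features, min_score = min_score, seed = seed
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The file round-trips losslessly through [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config` (for `read_config`).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

provenance_sidecar <- function(path, config, stage, inputs = character()) {
  side <- list(
    stage = stage,
    seed = config$seed,
    stage_seed = derive_seed(config$seed, stage),
    package_version = as.character(utils::packageVersion("dtiscreen")),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  jsonlite::write_json(side, paste0(path, ".provenance.json"), auto_unbox = TRUE)
}

#' Run one pipeline subcommand
#'
#' Subcommands: `simulate` (write a synthetic fixture bundle into
#' `out_dir`), `prioritize` (graph -> centrality -> shortlist TSV),
#' `featurize` (FASTA + ligand TSV -> feature matrix TSVs), `build-dataset`
#' (interactions -> deduplicated, weak-binder-relabeled, encoded dataset),
#' `train` (dataset -> model artifact), `evaluate` (model + dataset ->
#' metrics JSON), `screen` (model + shortlist + ligands -> ranked report).
#' Artifacts are written with provenance sidecars; on error, partial outputs
#' of the failing stage are removed.
#'
#' @param name Subcommand name.
#' @param config A [pipeline_config()].
#' @return Named character vector of artifact paths, invisibly.
#' @export
run_subcommand <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate", "prioritize", "featurize", "build-dataset",
             "train", "evaluate", "screen")
  if (!name %in% known) {
    abort(sprintf("unknown subcommand '%s'; expected one of: %s",
                  name, paste(known, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(name,
    "simulate" = stage_simulate, "prioritize" = stage_prioritize,
    "featurize" = stage_featurize, "build-dataset" = stage_build_dataset,
    "train" = stage_train, "evaluate" = stage_evaluate, "screen" = stage_screen
  )
  artifacts <- character(0)
  tryCatch(
    artifacts <- fn(config),
    error = function(e) {
      unlink(artifacts[file.exists(artifacts)])
      abort(sprintf("subcommand '%s' failed: %s", name, conditionMessage(e)))
    }
  )
  invisible(artifacts)
}

stage_simulate <- function(config) {
  write_fixture_bundle(config$out_dir, seed = config$seed)
}

require_input <- function(config, field) {
  p <- config[[field]]
  if (is.null(p) || !file.exists(p)) {
    abort(sprintf("missing input '%s' (path: %s)", field, p %||% "<unset>"))
  }
  p
}

stage_prioritize <- function(config) {
  gpath <- require_input(config, "graph")
  graph <- parse_string_links(gpath, min_score = config$min_score)
  cent <- centrality_table(graph)
  shortlist <- prioritize_targets(cent, sc_min = config$sc_min, k = config$top_k)
  out <- file.path(config$out_dir, "shortlist.tsv")
  write_shortlist(shortlist, out)
  cent_path <- file.path(config$out_dir, "centrality.tsv")
  readr::write_tsv(cent, cent_path, progress = FALSE)
  provenance_sidecar(out, config, "prioritize", gpath)
  c(shortlist = out, centrality = cent_path)
}

stage_featurize <- function(config) {
  fpath <- require_input(config, "fasta")
  lpath <- require_input(config, "ligands")
  proteins <- read_fasta(fpath)
  ligands <- read_ligands(lpath)
  pmat <- do.call(rbind, map(proteins$sequence, protein_features))
  rownames(pmat) <- proteins$id
  dmat <- do.call(rbind, map2(ligands$smiles, ligands$id,
                              function(s, i) drug_features(s, id = i)))
  rownames(dmat) <- ligands$id
  pout <- file.path(config$out_dir, "protein_features.tsv")
  dout <- file.path(config$out_dir, "drug_features.tsv")
  readr::write_tsv(as_tibble(pmat, rownames = "id"), pout, progress = FALSE)
  readr::write_tsv(as_tibble(dmat, rownames = "id"), dout, progress = FALSE)
  provenance_sidecar(pout, config, "featurize", c(fpath, lpath))
  c(protein_features = pout, drug_features = dout)
}

stage_build_dataset <- function(config) {
  ipath <- require_input(config, "interactions")
  fpath <- require_input(config, "fasta")
  lpath <- require_input(config, "ligands")
  records <- read_interactions(ipath)
  records <- dedup_interactions(records)
  weak <- !is.na(records$bioactivity_um) & records$bioactivity_um > config$threshold_um
  records$label[weak] <- "negative"
  out <- file.path(config$out_dir, "dataset.tsv")
  write_interactions(records, out)
  provenance_sidecar(out, config, "build-dataset", c(ipath, fpath, lpath))
  c(dataset = out)
}

stage_train <- function(config) {
  ipath <- require_input(config, "interactions")
  fpath <- require_input(config, "fasta")
  lpath <- require_input(config, "ligands")
  ds <- encode_dataset(dedup_interactions(read_interactions(ipath)),
                       read_fasta(fpath), read_ligands(lpath))
  model <- train_forest(ds, n_trees = config$n_trees,
                        max_features = min(config$max_features, ncol(ds$features)),
                        seed = derive_seed(config$seed, "train"))
  out <- file.path(config$out_dir, "model.rds")
  save_model(model, out)
  provenance_sidecar(out, config, "train", c(ipath, fpath, lpath))
  c(model = out)
}

stage_evaluate <- function(config) {
  mpath <- file.path(config$out_dir, "model.rds")
  if (!file.exists(mpath)) abort("no trained model in out_dir; run 'train' first")
  ipath <- require_input(config, "interactions")
  ds <- encode_dataset(dedup_interactions(read_interactions(ipath)),
                       read_fasta(require_input(config, "fasta")),
                       read_ligands(require_input(config, "ligands")))
  model <- load_model(mpath, manifest = colnames(ds$features))
  ev <- evaluate(model, ds)
  out <- file.path(config$out_dir, "evaluation.json")
  jsonlite::write_json(as.list(glance(ev)), out, auto_unbox = TRUE, digits = NA)
  provenance_sidecar(out, config, "evaluate", c(ipath, mpath))
  c(evaluation = out)
}

stage_screen <- function(config) {
  mpath <- file.path(config$out_dir, "model.rds")
  spath <- file.path(config$out_dir, "shortlist.tsv")
  if (!file.exists(mpath)) abort("no trained model in out_dir; run 'train' first")
  if (!file.exists(spath)) abort("no shortlist in out_dir; run 'prioritize' first")
  fpath <- require_input(config, "fasta")
  lpath <- require_input(config, "ligands")
  proteins <- read_fasta(fpath)
  ligands <- read_ligands(lpath)
  shortlist <- readr::read_tsv(spath, show_col_types = FALSE, progress = FALSE)
  targets <- intersect(shortlist$protein_id, proteins$id)
  if (length(targets) == 0) {
    # shortlist proteins may be graph nodes without sequences at desk scale;
    # fall back to the sequenced proteins so the screen remains runnable
    targets <- proteins$id
  }
  model <- load_model(mpath, manifest = NULL)
  if (is.null(model$feature_names)) abort("model artifact lacks feature names")
  pairs <- cartesian_candidates(targets, ligands$id)
  ranked <- rank_candidates(model, pairs, proteins, ligands)
  out <- file.path(config$out_dir, "predictions.tsv")
  export_report(ranked, out, seed = config$seed,
                model_hash = digest_vector(model$feature_names))
  provenance_sidecar(out, config, "screen", c(mpath, fpath, lpath))
  c(predictions = out)
}
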