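# All-against-all candidate screening and ranked repositioning report.

#' Build the all-against-all candidate pair set
#'
#' Crosses every target with every ligand in deterministic target-major,
#' ligand-minor order. Known pairs are removed only when `exclude_known` is
#' on; by default all pairs are screened, including drugs seen in training.
#'
#' @param targets Character vector of target ids (unique).
#' @param ligands Character vector of ligand ids (unique).
#' @param exclude_known Remove pairs listed in `known` (default off).
#' @param known A data frame with columns `drug_id`, `target_id` of known
#'   pairs (only used when `exclude_known` is on).
#' @return A tibble with columns `target_id`, `drug_id`.
#' @export
#' @examples
#' nrow(cartesian_candidates(paste0("t", 1:10), paste0("d", 1:3081))) # 30810
cartesian_candidates <- function(targets, ligands, exclude_known = FALSE,
                                 known = NULL) {
  check_unique_ids(targets, "target")
  check_unique_ids(ligands, "ligand")
  out <- tibble(
    target_id = rep(targets, each = length(ligands)),
    drug_id = rep(ligands, times = length(targets))
  )
  if (exclude_known && !is.null(known) && nrow(known) > 0) {
    key <- paste(out$target_id, out$drug_id, sep = "\r")
    known_key <- paste(known$target_id, known$drug_id, sep = "\r")
    out <- out[!key %in% known_key, , drop = FALSE]
  }
  out
}

#' Score and rank candidate pairs
#'
#' Featurizes each candidate pair (entities cached), scores it with the
#' trained forest, and returns pairs sorted by positive-class probability
#' descending. Ties are broken by `(target_id, drug_id)` ascending so reports
#' are reproducible. Probabilities are kept at full precision internally;
#' rounding to two decimals happens only at report time. Unfeaturizable pairs
#' are dropped with a message.
#'
#' @param model A [train_forest()] object.
#' @param pairs A tibble from [cartesian_candidates()].
#' @param protein_seqs A data frame with columns `id`, `sequence`.
#' @param ligand_table A data frame with columns `id`, `smiles`.
#' @param top_n Number of records to keep (default all).
#' @return A tibble of class `dti_predictions` with columns `target_id`,
#'   `drug_id`, `probability`; attribute `n_dropped` counts dropped pairs.
#' @export
rank_candidates <- function(model, pairs, protein_seqs, ligand_table,
                            top_n = Inf) {
  stopifnot(inherits(model, "dti_forest"))
  recs <- tibble(drug_id = pairs$drug_id, target_id = pairs$target_id,
                 label = "unknown")
  ds <- encode_dataset(recs, protein_seqs, ligand_table)
  n_dropped <- nrow(pairs) - nrow(ds$records)
  probs <- predict_probability(model, ds$features)
  out <- tibble(
    target_id = ds$records$target_id,
    drug_id = ds$records$drug_id,
    probability = probs
  )
  out <- arrange(out, desc(.data$probability), .data$target_id, .data$drug_id)
  if (is.finite(top_n)) out <- slice_head(out, n = top_n)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("dti_predictions", class(out))
  out
}

#' Export a ranked prediction report
#'
#' Writes a TSV with columns `target_id`, `drug_id`, `probability` (rounded
#' to 2 decimals at report time) preceded by `#`-prefixed provenance header
#' lines (record count, seed, model fingerprint).
#'
#' @param records A tibble of predictions.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @param model_hash Model fingerprint recorded in the header.
#' @return `path`, invisibly.
#' @export
export_report <- function(records, path, seed = NA, model_hash = NA) {
  header <- c(
    sprintf("# dtiscreen prediction report"),
    sprintf("# records: %d", nrow(records)),
    sprintf("# seed: %s", seed),
    sprintf("# model: %s", model_hash),
    "target_id\tdrug_id\tprobability"
  )
  rows <- sprintf("%s\t%s\t%.2f", records$target_id, records$drug_id,
                  records$probability)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a prediction report written by [export_report()]
#'
#' @param path Report path.
#' @return A tibble with columns `target_id`, `drug_id`, `probability`.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  readr::read_tsv(I(paste(lines, collapse = "\n")),
                  show_col_types = FALSE, progress = FALSE)
}

#' @export
autoplot.dti_predictions <- function(object, top_n = 20, ...) {
  df <- slice_head(object, n = top_n)
  df$pair <- factor(paste(df$target_id, df$drug_id, sep = " / "),
                    levels = rev(paste(df$target_id, df$drug_id, sep = " / ")))
  ggplot(df, aes(x = .data$probability, y = .data$pair)) +
    geom_col() +
    labs(x = "positive-class probability", y = NULL,
         title = sprintf("Top %d candidate drug-target interactions", nrow(df))) +
    theme_minimal()
}
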