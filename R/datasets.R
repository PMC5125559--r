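# Labeled DTI dataset construction: deduplication, weak-binder negatives,
# fingerprint redundancy screening, ratio-controlled negative allocation,
# and feature-matrix assembly.

#' Normalize a tibble of interaction records
#'
#' Ensures the canonical columns `drug_id`, `target_id`, `label`, `source`,
#' `bioactivity_um`, `measure` exist. `(drug_id, target_id)` is the identity
#' key of a record.
#'
#' @param records A data frame with at least `drug_id` and `target_id`.
#' @return A tibble with the canonical columns.
#' @export
interaction_records <- function(records) {
  records <- as_tibble(records)
  stopifnot(all(c("drug_id", "target_id") %in% names(records)))
  if (!"label" %in% names(records)) records$label <- "unknown"
  if (!"source" %in% names(records)) records$source <- NA_character_
  if (!"bioactivity_um" %in% names(records)) records$bioactivity_um <- NA_real_
  if (!"measure" %in% names(records)) records$measure <- NA_character_
  bad <- !is.na(records$bioactivity_um) & records$bioactivity_um <= 0
  if (any(bad)) abort("bioactivity values must be positive")
  select(records, "drug_id", "target_id", "label", "source", "bioactivity_um", "measure")
}

#' Deduplicate interaction records
#'
#' Keeps one record per `(drug_id, target_id)` key. When `set_order` is
#' given, the record from the earliest-listed source wins; otherwise the first
#' occurrence wins. If a key is labeled positive in one source and negative in
#' another, the positive record is kept and the conflict is reported.
#'
#' @param records Interaction records (see [interaction_records()]).
#' @param set_order Optional character vector of source names, earliest first.
#' @return A deduplicated tibble.
#' @export
dedup_interactions <- function(records, set_order = NULL) {
  records <- interaction_records(records)
  if (nrow(records) == 0) return(records)
  rank <- if (is.null(set_order)) rep(1L, nrow(records)) else {
    r <- match(records$source, set_order)
    ifelse(is.na(r), length(set_order) + 1L, r)
  }
  ord <- order(rank, seq_len(nrow(records)))
  records <- records[ord, , drop = FALSE]
  key <- paste(records$drug_id, records$target_id, sep = "\r")
  pos <- records$label == "positive"
  conflict_keys <- intersect(unique(key[pos]), unique(key[!pos]))
  if (length(conflict_keys) > 0) {
    inform(sprintf("%d label conflicts resolved by keeping the positive record",
                   length(conflict_keys)))
    # demote non-positive records of conflicted keys so a positive wins
    demote <- key %in% conflict_keys & !pos
    ord2 <- order(demote, seq_len(nrow(records)))
    records <- records[ord2, , drop = FALSE]
    key <- key[ord2]
  }
  records[!duplicated(key), , drop = FALSE]
}

#' Extract weak binders as negative examples
#'
#' Records whose experimental bioactivity is strictly greater than
#' `threshold_um` (default 10 uM) are considered weak binders and returned
#' relabeled as negatives. Records without a bioactivity value are skipped
#' with a message. An optional `bioactivity_unit` column ("uM", "nM", "mM")
#' converts values to uM before comparison.
#'
#' @param records Interaction records carrying `bioactivity_um`.
#' @param threshold_um Strict threshold in micromolar (default 10).
#' @return A tibble of negative-labeled records.
#' @export
filter_weak_binders <- function(records, threshold_um = 10.0) {
  recs <- as_tibble(records)
  unit_factor <- rep(1.0, nrow(recs))
  if ("bioactivity_unit" %in% names(recs)) {
    unit_factor <- dplyr::case_match(tolower(recs$bioactivity_unit),
      "nm" ~ 1e-3, "mm" ~ 1e3, "um" ~ 1.0, .default = 1.0
    )
  }
  recs <- interaction_records(recs)
  recs$bioactivity_um <- recs$bioactivity_um * unit_factor
  missing <- is.na(recs$bioactivity_um)
  if (any(missing)) {
    inform(sprintf("%d records without bioactivity skipped", sum(missing)))
  }
  out <- recs[!missing & recs$bioactivity_um > threshold_um, , drop = FALSE]
  out$label <- "negative"
  out
}

#' Tanimoto similarity of two binary fingerprints
#'
#' @param a,b Numeric/logical bit vectors of equal length.
#' @return `|a & b| / |a | b|` (0 when the union is empty).
#' @export
tanimoto_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Chemical redundancy report over a ligand library
#'
#' Computes pairwise Tanimoto similarity on 1024-bit path-based (FP2) binary
#' fingerprints over all unordered ligand pairs and reports the fraction of
#' pairs whose similarity strictly exceeds `cutoff`. Used to verify that a
#' training library is not dominated by near-duplicate chemistry.
#'
#' @param ligands A data frame with columns `id` and `smiles`.
#' @param cutoff Similarity threshold (default 0.85).
#' @return A tibble with `n_pairs`, `n_above`, `fraction_above`.
#' @export
fingerprint_redundancy_report <- function(ligands, cutoff = 0.85) {
  ligands <- as_tibble(ligands)
  n <- nrow(ligands)
  if (n < 2) return(tibble(n_pairs = 0L, n_above = 0L, fraction_above = 0))
  frags <- map_chr(ligands$smiles, function(s) parse_ligand("x", s)$fragment)
  fp <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", paste(frags, collapse = "\n"), identity),
    "FP2"
  )
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  sims <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sims <- c(sims, tanimoto_similarity(fp[i, ], fp[j, ]))
    }
  }
  tibble(
    n_pairs = length(sims),
    n_above = sum(sims > cutoff),
    fraction_above = sum(sims > cutoff) / length(sims)
  )
}

#' Allocate a negative pool across positive sets
#'
#' Every record of `negative_pool` is appended to exactly one positive set,
#' drawn at random without replacement. Set i (in order) receives
#' `round(ratio * nrow(positive_sets[[i]]))` negatives; the last set receives
#' the remainder, reproducing an approximate negative-to-positive ratio. An
#' explicit per-set `override` of negative counts is available for exact
#' replication of published splits. If the pool cannot fill the quotas, the
#' allocation falls back to proportional quotas with a warning.
#'
#' @param positive_sets Ordered (optionally named) list of record tibbles.
#' @param negative_pool Tibble of negative records, disjoint by key from all
#'   positives.
#' @param ratio Negative-to-positive ratio (default 1.5).
#' @param seed Integer seed for the random draw.
#' @param override Optional integer vector of per-set negative counts.
#' @return A list of tibbles: each positive set with its negatives appended.
#' @export
allocate_negatives <- function(positive_sets, negative_pool, ratio = 1.5,
                               seed = 1L, override = NULL) {
  stopifnot(ratio > 0, length(positive_sets) >= 1)
  pool <- interaction_records(negative_pool)
  pos_keys <- unlist(map(positive_sets, function(s) paste(s$drug_id, s$target_id, sep = "\r")))
  pool_keys <- paste(pool$drug_id, pool$target_id, sep = "\r")
  if (any(pool_keys %in% pos_keys)) abort("negative pool overlaps a positive set by key")
  k <- length(positive_sets)
  n_pool <- nrow(pool)
  quotas <- if (!is.null(override)) {
    stopifnot(length(override) == k)
    as.integer(override)
  } else {
    q <- map_dbl(positive_sets, function(s) round(ratio * nrow(s)))
    q[k] <- n_pool - sum(q[-k])
    as.integer(q)
  }
  if (any(quotas < 0) || sum(quotas) > n_pool) {
    warn("negative pool smaller than requested quotas; using proportional allocation")
    sizes <- map_dbl(positive_sets, nrow)
    quotas <- as.integer(floor(n_pool * sizes / sum(sizes)))
    quotas[k] <- n_pool - sum(quotas[-k])
  }
  perm <- withr::with_seed(seed, sample.int(n_pool))
  leftover <- n_pool - sum(quotas)
  out <- vector("list", k)
  offset <- 0L
  for (i in seq_len(k)) {
    take <- quotas[i] + if (i == k) leftover else 0L
    idx <- perm[seq_len(take) + offset]
    offset <- offset + take
    out[[i]] <- bind_rows(interaction_records(positive_sets[[i]]), pool[idx, , drop = FALSE])
  }
  names(out) <- names(positive_sets)
  out
}

#' Encode interaction records as a labeled feature dataset
#'
#' Each row is the 432-value protein feature block of the target followed by
#' the 323-value drug feature block of the ligand (755 features total).
#' Entities are featurized once and cached, so repeated drugs/targets cost
#' nothing extra. Records whose target sequence or drug SMILES is missing or
#' fails featurization are dropped with a message.
#'
#' @param records Interaction records.
#' @param protein_seqs A data frame with columns `id`, `sequence`.
#' @param ligand_table A data frame with columns `id`, `smiles`.
#' @return An object of class `dti_dataset`: a list with `records` (tibble),
#'   `features` (numeric matrix, 755 columns) and `labels` (0/1 integer
#'   vector, 1 = positive). The number of entity featurizations performed is
#'   attached as attribute `n_featurizations`.
#' @export
encode_dataset <- function(records, protein_seqs, ligand_table) {
  records <- interaction_records(records)
  protein_seqs <- as_tibble(protein_seqs)
  ligand_table <- as_tibble(ligand_table)
  key <- paste(records$drug_id, records$target_id, sep = "\r")
  if (anyDuplicated(key)) abort("duplicate (drug_id, target_id) keys; dedup first")
  prot_cache <- new.env(parent = emptyenv())
  drug_cache <- new.env(parent = emptyenv())
  n_feat <- 0L
  get_cached <- function(cache, id, fn) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    val <- tryCatch(fn(), error = function(e) e)
    n_feat <<- n_feat + 1L
    cache[[id]] <- val
    val
  }
  rows <- vector("list", nrow(records))
  ok <- logical(nrow(records))
  dropped <- character(0)
  for (i in seq_len(nrow(records))) {
    tid <- records$target_id[i]
    did <- records$drug_id[i]
    seq_i <- protein_seqs$sequence[match(tid, protein_seqs$id)]
    smi_i <- ligand_table$smiles[match(did, ligand_table$id)]
    if (is.na(seq_i) || is.na(smi_i)) {
      dropped <- c(dropped, paste0(did, "/", tid))
      next
    }
    pf <- get_cached(prot_cache, tid, function() protein_features(seq_i))
    df <- get_cached(drug_cache, did, function() drug_features(smi_i, id = did))
    if (inherits(pf, "error") || inherits(df, "error")) {
      dropped <- c(dropped, paste0(did, "/", tid))
      next
    }
    rows[[i]] <- c(pf, df)
    ok[i] <- TRUE
  }
  if (length(dropped) > 0) {
    inform(sprintf("dropped %d unfeaturizable records: %s",
                   length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  features <- if (any(ok)) do.call(rbind, rows[ok]) else
    matrix(numeric(0), nrow = 0, ncol = 755)
  records <- records[ok, , drop = FALSE]
  out <- structure(list(
    records = records,
    features = features,
    labels = as.integer(records$label == "positive")
  ), class = "dti_dataset")
  attr(out, "n_featurizations") <- n_feat
  stopifnot(ncol(out$features) == 755 || nrow(out$features) == 0)
  out
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat(sprintf("<dti_dataset: %d records (%d positive), %d features>\n",
              nrow(x$records), sum(x$labels), ncol(x$features)))
  invisible(x)
}

#' @export
as_tibble.dti_dataset <- function(x, ...) x$records

#' Read interaction records from TSV
#'
#' Expects columns `drug_id`, `target_id` and optionally `label`, `source`,
#' `bioactivity_um`, `measure`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of interaction records.
#' @export
read_interactions <- function(path) {
  interaction_records(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write interaction records to TSV
#'
#' @param records Interaction records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  readr::write_tsv(interaction_records(records), path, progress = FALSE)
  invisible(path)
}

#' Read a ligand table (`id<TAB>smiles`)
#'
#' @param path Path to a TSV file with columns `id` and `smiles` (header
#'   optional).
#' @return A tibble with columns `id`, `smiles`.
#' @export
read_ligands <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^id\\b", first)
  if (has_header) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, col_names = c("id", "smiles"),
                    show_col_types = FALSE, progress = FALSE)
  }
}
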