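# Synthetic fixtures: desk-scale inputs for every pipeline stage, so the
# whole pipeline is testable without external downloads. Generators are
# deterministic under a seed, and every writer round-trips through the
# package's own readers.

#' Generate a graph of known topology
#'
#' @param kind One of `"path"`, `"ring"`, `"star"`, `"complete"`,
#'   `"random"` (Erdos-Renyi G(n, p)), `"two_community"` (stochastic block
#'   model with dense blocks and sparse cross edges).
#' @param n Number of nodes.
#' @param seed Seed for the random kinds.
#' @param p Edge probability for `"random"` (default 0.2).
#' @return An [interactome()] with nodes named `P001`, `P002`, ...
#' @export
make_graph <- function(kind, n, seed = 1L, p = 0.2) {
  stopifnot(n >= 1)
  ig <- switch(kind,
    path = igraph::make_lattice(length = n, dim = 1),
    ring = igraph::make_ring(n),
    star = igraph::make_star(n, mode = "undirected"),
    complete = igraph::make_full_graph(n),
    random = withr::with_seed(seed, igraph::sample_gnp(n, p)),
    two_community = withr::with_seed(seed, {
      sizes <- c(ceiling(n / 2), floor(n / 2))
      igraph::sample_sbm(n, pref.matrix = matrix(c(0.35, 0.03, 0.03, 0.35), 2),
                         block.sizes = sizes)
    }),
    abort(sprintf("unknown graph kind: %s", kind))
  )
  names <- sprintf("P%03d", seq_len(n))
  el <- igraph::as_edgelist(ig, names = FALSE)
  interactome(
    tibble(protein1 = names[el[, 1]], protein2 = names[el[, 2]]),
    nodes = names
  )
}

#' Random protein sequence
#'
#' Uniform draw over the 20-residue alphabet.
#'
#' @param length Sequence length (>= 31 for full-pipeline use, so the Moran
#'   block is computable).
#' @param seed Integer seed.
#' @return A single sequence string.
#' @export
random_protein <- function(length, seed = 1L) {
  stopifnot(length >= 1)
  withr::with_seed(seed, paste(sample(AA_ALPHABET, length, replace = TRUE),
                               collapse = ""))
}

#' A table of random proteins
#'
#' @param n Number of proteins.
#' @param length Sequence length for each.
#' @param seed Integer seed.
#' @return A tibble with columns `id` (`T001`, ...) and `sequence`.
#' @export
random_proteins <- function(n, length = 60, seed = 1L) {
  tibble(
    id = sprintf("T%03d", seq_len(n)),
    sequence = map_chr(seq_len(n), function(i) random_protein(length, seed = seed + i))
  )
}

#' Embedded fixture ligand table
#'
#' Twenty small drug-like molecules with valid SMILES, including salt forms
#' (to exercise the largest-fragment rule) and a range of ring systems and
#' heteroatoms. The table is static and versioned with the package.
#'
#' @return A tibble with columns `id` and `smiles`.
#' @export
fixture_ligands <- function() {
  tibble::tribble(
    ~id, ~smiles,
    "ethanol", "CCO",
    "benzene", "c1ccccc1",
    "phenol", "Oc1ccccc1",
    "toluene", "Cc1ccccc1",
    "pyridine", "c1ccncc1",
    "imidazole", "c1cnc[nH]1",
    "furan", "c1ccoc1",
    "thiophene", "c1ccsc1",
    "naphthalene", "c1ccc2ccccc2c1",
    "acetic_acid", "CC(=O)O",
    "urea", "NC(N)=O",
    "glycine", "NCC(=O)O",
    "aspirin", "CC(=O)Oc1ccccc1C(=O)O",
    "paracetamol", "CC(=O)Nc1ccc(O)cc1",
    "ibuprofen", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    "caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    "nicotine", "CN1CCCC1c1cccnc1",
    "benzamidine", "NC(=N)c1ccccc1",
    "sodium_benzoate", "[Na+].[O-]C(=O)c1ccccc1",
    "trifluoperazine_2hcl", "Cl.Cl.CN1CCN(CCCN2c3ccccc3Sc3ccc(C(F)(F)F)cc32)CC1"
  )
}

#' Synthetic labeled DTI dataset
#'
#' Pairs random proteins with the fixture ligands, featurizes every pair
#' through the real 755-descriptor pipeline, and draws labels from a logistic
#' model on a fixed sparse subset of the true computed features (the
#' amino-acid-composition block), scaled by `effect_size`. With
#' `effect_size = 0` labels are independent coin flips; large effect sizes
#' make labels a near-deterministic function of the features. Signal flows
#' through real computed features (not appended dummy columns), so the
#' featurization-to-model path is what downstream tests exercise. Records
#' carry synthetic bioactivities (positives below, negatives above 10 uM) so
#' weak-binder filtering is exercisable.
#'
#' @param n_pos,n_neg Number of positive and negative records (>= 1).
#' @param effect_size Signal strength (>= 0).
#' @param seed Integer seed; fixtures are byte-identical under a fixed seed.
#' @param seq_length Protein sequence length (default 60).
#' @param n_proteins Number of distinct proteins to draw entities from; the
#'   default provides about 1.5 candidate pairs per requested record, so
#'   proteins recur across records. Larger values reduce per-protein record
#'   multiplicity (useful when protein-identity memorization must not stand
#'   in for feature signal).
#' @return A `dti_dataset` (see [encode_dataset()]) with the generating
#'   entities attached as attributes `proteins` and `ligands`.
#' @export
synthetic_dti_dataset <- function(n_pos, n_neg, effect_size = 2, seed = 1L,
                                  seq_length = 60, n_proteins = NULL) {
  stopifnot(n_pos >= 1, n_neg >= 1, effect_size >= 0)
  ligands <- fixture_ligands()
  n_total <- n_pos + n_neg
  n_prot <- n_proteins %||% max(20, ceiling(3 * n_total / (2 * nrow(ligands))))
  proteins <- random_proteins(n_prot, length = seq_length, seed = derive_seed(seed, "proteins"))
  pairs <- cartesian_candidates(proteins$id, ligands$id)
  recs <- tibble(drug_id = pairs$drug_id, target_id = pairs$target_id,
                 label = "unknown", source = "synthetic")
  ds <- encode_dataset(recs, proteins, ligands)
  aac_idx <- grep("^aac_", colnames(ds$features))
  w <- rep(c(1, -1), length.out = length(aac_idx))
  z <- as.vector(ds$features[, aac_idx] %*% w)
  z <- (z - mean(z)) / (stats::sd(z) + 1e-12)
  prob <- plogis(effect_size * z)
  lab <- withr::with_seed(derive_seed(seed, "labels"),
                          as.integer(runif(length(prob)) < prob))
  pos_idx <- which(lab == 1)
  neg_idx <- which(lab == 0)
  if (length(pos_idx) < n_pos || length(neg_idx) < n_neg) {
    abort("not enough candidate pairs to satisfy n_pos/n_neg; lower the counts")
  }
  sel <- withr::with_seed(derive_seed(seed, "select"), {
    c(sample(pos_idx, n_pos), sample(neg_idx, n_neg))
  })
  out <- subset_dataset(ds, sort(sel))
  lab_sel <- lab[sort(sel)]
  bio <- withr::with_seed(derive_seed(seed, "bioactivity"), {
    ifelse(lab_sel == 1, runif(length(lab_sel), 0.001, 9),
           runif(length(lab_sel), 10.5, 500))
  })
  out$records$label <- ifelse(lab_sel == 1, "positive", "negative")
  out$records$bioactivity_um <- bio
  out$records$measure <- "IC50"
  out$labels <- lab_sel
  attr(out, "proteins") <- proteins
  attr(out, "ligands") <- ligands
  out
}

#' Write a complete fixture bundle to a directory
#'
#' Emits a STRING-dialect graph file, a FASTA of protein sequences, a ligand
#' TSV and an interaction TSV, all generated from one seed. Each file
#' round-trips through the package's own readers.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param n_nodes Graph size (default 40).
#' @param n_pos,n_neg Dataset composition (defaults 60/90).
#' @param effect_size Label signal strength (default 6).
#' @return Named character vector of the file paths written.
#' @export
write_fixture_bundle <- function(dir, seed = 1L, n_nodes = 40,
                                 n_pos = 60, n_neg = 90, effect_size = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  graph <- make_graph("random", n_nodes, seed = derive_seed(seed, "graph"), p = 0.15)
  ds <- synthetic_dti_dataset(n_pos, n_neg, effect_size = effect_size, seed = seed)
  proteins <- attr(ds, "proteins")
  ligands <- attr(ds, "ligands")
  paths <- c(
    graph = file.path(dir, "graph.txt"),
    fasta = file.path(dir, "proteins.fasta"),
    ligands = file.path(dir, "ligands.tsv"),
    interactions = file.path(dir, "interactions.tsv")
  )
  write_string_links(graph, paths[["graph"]])
  write_fasta(proteins, paths[["fasta"]])
  readr::write_tsv(ligands, paths[["ligands"]], progress = FALSE)
  write_interactions(ds$records, paths[["interactions"]])
  paths
}

#' Constructed fixture for hyperparameter-selection sanity checks
#'
#' A labeled synthetic dataset plus a small hyperparameter grid constructed
#' so that the reference configuration (150 trees, 100 split features) wins
#' the grid search: the competitors are deliberately under-sized single-tree
#' forests at several subspace sizes, whose high variance on noisy labels
#' costs them a large, stable accuracy margin. At desk scale, accuracy contrasts
#' between equally sized fully-grown probability forests that differ only in
#' `max_features` are statistically thin, so the fixture contrasts forest
#' size, where the margin is large and stable.
#'
#' @param seed Integer seed for the dataset draw.
#' @return A list with elements `dataset` and `grid`.
#' @export
grid_search_fixture <- function(seed = 11L) {
  dataset <- synthetic_dti_dataset(150, 150, effect_size = 2, seed = seed)
  grid <- tibble(
    n_trees = c(1L, 1L, 1L, 150L),
    max_features = c(27L, 100L, 755L, 100L)
  )
  list(dataset = dataset, grid = grid)
}
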