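# Protein sequence descriptors: 20 AAC + 240 Moran autocorrelation + 147 CTD.

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")

.tables_env <- new.env(parent = emptyenv())

#' Amino-acid property scales used by the Moran autocorrelation block
#'
#' Eight classic per-residue physicochemical scales (hydrophobicity, average
#' flexibility, polarizability, free energy of solution in water, residue
#' accessible surface area, residue volume, steric parameter, relative
#' mutability), shipped as a versioned TSV. Scales are z-score normalized over
#' the 20 residues (population standard deviation) before use, so Moran
#' descriptors are invariant to positive affine transforms of the raw scales.
#'
#' @param normalized Return normalized (default) or raw values.
#' @return A tibble with a `scale` column and one column per residue.
#' @export
property_scales <- function(normalized = TRUE) {
  if (is.null(.tables_env$scales)) {
    .tables_env$scales <- read_versioned_tsv("aa_property_scales.tsv",
      md5 = "eb097e63eaa4e586f63ec18f0a13846b")
  }
  raw <- .tables_env$scales
  if (!normalized) return(raw)
  vals <- as.matrix(raw[, AA_ALPHABET])
  mu <- rowMeans(vals)
  sd_pop <- sqrt(rowMeans((vals - mu)^2))
  norm <- (vals - mu) / sd_pop
  out <- as_tibble(as.data.frame(norm))
  out <- dplyr::bind_cols(raw["scale"], out)
  out
}

#' CTD residue group partitions
#'
#' Seven attributes (hydrophobicity, normalized van der Waals volume,
#' polarity, polarizability, charge, secondary structure, solvent
#' accessibility), each partitioning the 20 residues into three disjoint
#' groups, following the classic composition/transition/distribution
#' convention.
#'
#' @return A tibble with columns `attribute`, `group1`, `group2`, `group3`.
#' @export
ctd_groups <- function() {
  if (is.null(.tables_env$ctd)) {
    .tables_env$ctd <- read_versioned_tsv("ctd_groups.tsv",
      md5 = "8c29a693fdd0e138dbedc14ca0f67a38")
    # partition sanity: each attribute covers all 20 residues exactly once
    for (i in seq_len(nrow(.tables_env$ctd))) {
      r <- .tables_env$ctd[i, ]
      res <- unlist(strsplit(paste0(r$group1, r$group2, r$group3), ""))
      if (length(res) != 20 || anyDuplicated(res) || !setequal(res, AA_ALPHABET)) {
        abort(sprintf("CTD attribute %s does not partition the 20 residues", r$attribute))
      }
    }
  }
  .tables_env$ctd
}

# validate a protein sequence, returning the residue vector
check_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  res <- strsplit(seq, "")[[1]]
  if (length(res) < 1) abort("empty protein sequence")
  bad <- which(!res %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid residue '%s' at position %d", res[bad[[1]]], bad[[1]]
    ))
  }
  res
}

#' Amino-acid composition (20 descriptors)
#'
#' Fraction of each residue type in the sequence, in fixed alphabetical
#' residue order (A, C, D, ..., Y). Values sum to 1.
#'
#' @param seq Protein sequence string over the 20-residue alphabet.
#' @return Named numeric vector of length 20 (names `aac_A` ... `aac_Y`).
#' @export
#' @examples
#' amino_acid_composition("ACDEFGHIKLMNPQRSTVWY")
amino_acid_composition <- function(seq) {
  res <- check_sequence(seq)
  counts <- table(factor(res, levels = AA_ALPHABET))
  setNames(as.numeric(counts) / length(res), paste0("aac_", AA_ALPHABET))
}

#' Moran autocorrelation descriptors (240 = 8 scales x 30 lags)
#'
#' For a normalized property scale P and lag d,
#' I(d) = \[(1/(N-d)) sum_i (P_i - Pbar)(P_(i+d) - Pbar)\] /
#' \[(1/N) sum_i (P_i - Pbar)^2\],
#' where Pbar is the mean of the property over the sequence. Zero-variance
#' sequences (e.g. homopolymers) yield 0 by convention. Ordering is
#' scale-major, lag-minor.
#'
#' @param seq Protein sequence string; must be longer than `max_lag`.
#' @param scales Normalized property scales, as from [property_scales()].
#' @param max_lag Largest lag (default 30).
#' @return Named numeric vector of length `8 * max_lag`.
#' @export
moran_autocorrelation <- function(seq, scales = property_scales(), max_lag = 30) {
  res <- check_sequence(seq)
  n <- length(res)
  if (n <= max_lag) {
    abort(sprintf("sequence length %d too short for Moran lags; need at least %d", n, max_lag + 1))
  }
  out <- numeric(0)
  for (i in seq_len(nrow(scales))) {
    sc_name <- scales$scale[[i]]
    vals <- as.numeric(scales[i, AA_ALPHABET])
    p <- vals[match(res, AA_ALPHABET)]
    pbar <- mean(p)
    denom <- mean((p - pbar)^2)
    block <- numeric(max_lag)
    if (denom > 1e-12) {
      centered <- p - pbar
      for (d in seq_len(max_lag)) {
        block[d] <- mean(centered[1:(n - d)] * centered[(1 + d):n]) / denom
      }
    }
    names(block) <- sprintf("moran_%s_d%d", sc_name, seq_len(max_lag))
    out <- c(out, block)
  }
  out
}

#' CTD descriptors (147 = 7 attributes x 21)
#'
#' Each attribute maps residues into three physicochemical groups. Per
#' attribute: Composition is the fraction of residues in each group (3);
#' Transition is, for each unordered group pair, the number of adjacent
#' residue pairs spanning the two groups divided by N-1 (3); Distribution is,
#' for each group, the sequence position (as a percentage of N) of the first
#' occurrence and of the occurrences at the 25/50/75/100% quantiles of that
#' group's occurrence list (5 values, quantile index `ceiling(q * count)`,
#' all 0 when the group is absent). Ordering is attribute-major.
#'
#' @param seq Protein sequence string, length >= 2.
#' @param attributes Group partitions, as from [ctd_groups()].
#' @return Named numeric vector of length 147.
#' @export
ctd_descriptors <- function(seq, attributes = ctd_groups()) {
  res <- check_sequence(seq)
  n <- length(res)
  if (n < 2) abort("CTD descriptors need a sequence of length >= 2")
  out <- numeric(0)
  for (i in seq_len(nrow(attributes))) {
    at <- attributes[i, ]
    groups <- list(
      strsplit(at$group1, "")[[1]],
      strsplit(at$group2, "")[[1]],
      strsplit(at$group3, "")[[1]]
    )
    g <- integer(n)
    for (k in 1:3) g[res %in% groups[[k]]] <- k
    comp <- as.numeric(table(factor(g, levels = 1:3))) / n
    pairs <- cbind(g[-n], g[-1])
    trans <- c(
      sum((pairs[, 1] == 1 & pairs[, 2] == 2) | (pairs[, 1] == 2 & pairs[, 2] == 1)),
      sum((pairs[, 1] == 1 & pairs[, 2] == 3) | (pairs[, 1] == 3 & pairs[, 2] == 1)),
      sum((pairs[, 1] == 2 & pairs[, 2] == 3) | (pairs[, 1] == 3 & pairs[, 2] == 2))
    ) / (n - 1)
    dist <- numeric(0)
    for (k in 1:3) {
      occ <- which(g == k)
      m <- length(occ)
      if (m == 0) {
        d5 <- rep(0, 5)
      } else {
        idx <- c(1, ceiling(0.25 * m), ceiling(0.5 * m), ceiling(0.75 * m), m)
        idx <- pmax(idx, 1L)
        d5 <- 100 * occ[idx] / n
      }
      dist <- c(dist, d5)
    }
    block <- c(comp, trans, dist)
    names(block) <- paste0(
      "ctd_", at$attribute, "_",
      c(
        "C1", "C2", "C3", "T12", "T13", "T23",
        as.vector(outer(c("first", "q25", "q50", "q75", "q100"), 1:3,
          function(q, gg) paste0("D", gg, "_", q)
        ))
      )
    )
    out <- c(out, block)
  }
  out
}

#' Pseudo-amino-acid composition (25 = 20 + lambda descriptors)
#'
#' Chou-type pseudo-amino-acid composition: the 20 residue frequencies
#' augmented with `lambda` sequence-order correlation factors computed from
#' three standardized residue properties (hydrophobicity, hydrophilicity,
#' side-chain mass). The correlation factor at tier k is the mean, over
#' positions i, of the mean squared property difference between residues i
#' and i+k. All 25 values are jointly normalized so they sum to 1:
#' the first 20 are f_r / (1 + w * sum(theta)), the last lambda are
#' w * theta_k / (1 + w * sum(theta)).
#'
#' @param seq Protein sequence string, length > `lambda`.
#' @param lambda Number of sequence-order tiers (default 5).
#' @param w Weight of the sequence-order terms (default 0.05).
#' @return Named numeric vector of length `20 + lambda`.
#' @export
pseudo_aac <- function(seq, lambda = 5, w = 0.05) {
  res <- check_sequence(seq)
  n <- length(res)
  if (n <= lambda) {
    abort(sprintf("sequence length %d too short for pseudo-AAC; need at least %d", n, lambda + 1))
  }
  if (is.null(.tables_env$paac)) {
    .tables_env$paac <- read_versioned_tsv("paac_scales.tsv",
      md5 = "48f0ac75276295454bc2100b87c5deff")
  }
  raw <- as.matrix(.tables_env$paac[, AA_ALPHABET])
  mu <- rowMeans(raw)
  sd_pop <- sqrt(rowMeans((raw - mu)^2))
  norm <- (raw - mu) / sd_pop
  prop <- norm[, match(res, AA_ALPHABET), drop = FALSE] # 3 x n
  theta <- map_dbl(seq_len(lambda), function(k) {
    d2 <- (prop[, (1 + k):n, drop = FALSE] - prop[, 1:(n - k), drop = FALSE])^2
    mean(colMeans(d2))
  })
  f <- as.numeric(table(factor(res, levels = AA_ALPHABET))) / n
  denom <- 1 + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  setNames(out, c(paste0("paac_", AA_ALPHABET), paste0("paac_theta", seq_len(lambda))))
}

#' Full protein feature block (432 descriptors)
#'
#' Concatenation of amino-acid composition (20), Moran autocorrelation (240),
#' CTD (147) and pseudo-amino-acid composition (25) descriptors. The fourth
#' sub-block closes the gap between the three classic blocks (407 values) and
#' the contractual 432-wide protein representation.
#'
#' @param seq Protein sequence string, length > 30.
#' @param clean If `TRUE`, nonstandard residues (B, J, O, U, X, Z) are
#'   stripped before featurization (with a message); by default they are
#'   rejected.
#' @return Named numeric vector of length 432.
#' @export
protein_features <- function(seq, clean = FALSE) {
  if (clean) {
    res <- strsplit(seq, "")[[1]]
    drop <- res %in% NONSTANDARD_AA
    if (any(drop)) {
      inform(sprintf("stripped %d nonstandard residues", sum(drop)))
      seq <- paste(res[!drop], collapse = "")
    }
  }
  out <- c(
    amino_acid_composition(seq),
    moran_autocorrelation(seq),
    ctd_descriptors(seq),
    pseudo_aac(seq)
  )
  stopifnot(length(out) == 432)
  out
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file. Record ids are the description line up to
#'   the first whitespace.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  tibble(id = ids, sequence = unname(as.character(set)))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
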