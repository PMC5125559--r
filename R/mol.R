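# Ligand parsing: SMILES -> molecular graph.
#
# OpenBabel (via ChemmineOB) supplies three views of each structure that are
# merged into one graph object: an SDF block for kekulized bond orders and
# formal charges, a MOL2 block for SYBYL atom types, aromaticity and Gasteiger
# partial charges, and prop_OB for whole-molecule properties (MW, logP, MR,
# TPSA, H-bond donor/acceptor counts). Implicit hydrogen counts are derived
# from kekulized bond orders with a standard valence model.

.mol_cache <- new.env(parent = emptyenv())

STANDARD_VALENCE <- list(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5), S = c(2, 4, 6),
  Cl = 1, Br = 1, I = 1, Se = c(2, 4, 6), As = c(3, 5)
)
VALENCE_ELECTRONS <- c(
  B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5, S = 6,
  Cl = 7, Br = 7, I = 7, Se = 6, As = 5
)
ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, As = 33, Se = 34, Br = 35,
  Sn = 50, I = 53
)
# Kier alpha contributions (covalent radius ratio to sp3 carbon, minus 1)
KIER_ALPHA <- c(
  C.sp2 = -0.13, C.sp = -0.22, N.sp3 = -0.04, N.sp2 = -0.20, N.sp = -0.29,
  O.sp3 = -0.04, O.sp2 = -0.20, F.sp3 = -0.07, P.sp3 = 0.43, S.sp3 = 0.35,
  S.sp2 = 0.22, Cl.sp3 = 0.29, Br.sp3 = 0.48, I.sp3 = 0.73
)

ob_convert <- function(from, to, source) {
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, source))
  out
}

split_fragments <- function(smiles) {
  # split outside of brackets is unnecessary: '.' never occurs inside []
  strsplit(smiles, ".", fixed = TRUE)[[1]]
}

# rough heavy-atom count used only to pick the largest fragment
fragment_size <- function(frag) {
  sdf <- ob_convert("SMI", "SDF", paste(frag, "f"))
  if (!nzchar(sdf)) return(NA_integer_)
  counts <- parse_sdf_counts(sdf)
  counts$n_atoms
}

parse_sdf_counts <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  cl <- lines[[4]]
  list(
    n_atoms = as.integer(substr(cl, 1, 3)),
    n_bonds = as.integer(substr(cl, 4, 6)),
    lines = lines
  )
}

parse_sdf <- function(sdf) {
  p <- parse_sdf_counts(sdf)
  lines <- p$lines
  na <- p$n_atoms
  nb <- p$n_bonds
  atom_lines <- lines[4 + seq_len(na)]
  element <- trimws(substr(atom_lines, 32, 34))
  bond_lines <- if (nb > 0) lines[4 + na + seq_len(nb)] else character()
  a1 <- as.integer(substr(bond_lines, 1, 3))
  a2 <- as.integer(substr(bond_lines, 4, 6))
  order <- as.integer(substr(bond_lines, 7, 9))
  formal <- integer(na)
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl2 in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", cl2)), "\\s+")[[1]])
    idx <- f[seq(1, length(f), by = 2)]
    val <- f[seq(2, length(f), by = 2)]
    formal[idx] <- val
  }
  list(element = element, formal = formal,
       bonds = tibble(a1 = a1, a2 = a2, order = order))
}

parse_mol2 <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  ai <- which(lines == "@<TRIPOS>ATOM")
  bi <- which(lines == "@<TRIPOS>BOND")
  stopifnot(length(ai) == 1, length(bi) == 1)
  stop_at <- c(grep("^@<TRIPOS>", lines), length(lines) + 1)
  a_end <- min(stop_at[stop_at > ai]) - 1
  b_end <- min(stop_at[stop_at > bi]) - 1
  parse_fields <- function(ln) strsplit(trimws(ln), "\\s+")
  af <- parse_fields(lines[(ai + 1):a_end])
  af <- af[lengths(af) >= 9]
  bf <- if (b_end > bi) parse_fields(lines[(bi + 1):b_end]) else list()
  bf <- bf[lengths(bf) >= 4]
  list(
    sybyl = map_chr(af, 6),
    charge = as.numeric(map_chr(af, 9)),
    bond_a1 = as.integer(map_chr(bf, 2)),
    bond_a2 = as.integer(map_chr(bf, 3)),
    bond_type = map_chr(bf, 4)
  )
}

#' Parse a ligand from SMILES
#'
#' Builds a molecular-graph handle used by all drug-descriptor functions.
#' Multi-fragment inputs (salts) are reduced to the largest fragment before
#' descriptor computation; hydrogens are implicit. Parsed structures are
#' cached per SMILES string, so repeated featurization of the same ligand is
#' cheap.
#'
#' @param id Ligand identifier.
#' @param smiles SMILES string.
#' @return An object of class `mol` with atom and bond tables.
#' @export
#' @examples
#' m <- parse_ligand("ethanol", "CCO")
#' m$atoms
parse_ligand <- function(id, smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles))) {
    abort("empty SMILES string")
  }
  smiles <- trimws(smiles)
  cached <- .mol_cache[[smiles]]
  if (!is.null(cached)) {
    cached$id <- id
    return(cached)
  }
  frags <- split_fragments(smiles)
  if (length(frags) > 1) {
    sizes <- map_dbl(frags, fragment_size)
    if (all(is.na(sizes))) abort(sprintf("unparsable SMILES: %s", smiles))
    # prefer carbon-containing (organic) fragments
    organic <- grepl("[Cc]", gsub("Cl|Ca|Cd|Sc", "", frags))
    pick <- if (any(organic & !is.na(sizes))) {
      which(organic)[which.max(sizes[organic])]
    } else {
      which.max(sizes)
    }
    frag <- frags[[pick]]
  } else {
    frag <- frags[[1]]
  }
  sdf <- ob_convert("SMI", "SDF", paste(frag, id))
  mol2 <- ob_convert("SMI", "MOL2", paste(frag, id))
  if (!nzchar(sdf) || !nzchar(mol2)) abort(sprintf("unparsable SMILES: %s", smiles))
  s <- parse_sdf(sdf)
  m <- parse_mol2(mol2)
  na <- length(s$element)
  if (length(m$sybyl) != na) abort(sprintf("inconsistent structure perception for %s", smiles))
  props <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", frag, identity))

  bonds <- s$bonds
  n_bonds <- nrow(bonds)
  in_ring <- bond_in_ring(na, bonds)
  bond_aromatic <- logical(n_bonds)
  if (n_bonds > 0) {
    # MOL2 flags conjugated exocyclic bonds (amide C-N, carbonyl C=O,
    # carboxylate resonance) as "ar" too; true aromaticity is ring-bound,
    # and kekulized SDF orders describe the exocyclic cases correctly.
    # SDF and MOL2 may order bonds differently: match by endpoints.
    key <- function(x, y) paste(pmin(x, y), pmax(x, y))
    ar_keys <- key(m$bond_a1, m$bond_a2)[m$bond_type == "ar"]
    bond_aromatic <- key(bonds$a1, bonds$a2) %in% ar_keys & in_ring
  }
  atom_aromatic <- logical(na)
  if (n_bonds > 0) {
    atom_aromatic[unique(c(bonds$a1[bond_aromatic], bonds$a2[bond_aromatic]))] <- TRUE
  }
  # implicit hydrogens from kekulized valence
  degree <- integer(na)
  bondsum <- numeric(na)
  for (i in seq_len(n_bonds)) {
    degree[bonds$a1[i]] <- degree[bonds$a1[i]] + 1L
    degree[bonds$a2[i]] <- degree[bonds$a2[i]] + 1L
    bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + bonds$order[i]
    bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + bonds$order[i]
  }
  nH <- integer(na)
  for (i in seq_len(na)) {
    el <- s$element[i]
    allowed <- STANDARD_VALENCE[[el]]
    if (is.null(allowed)) { nH[i] <- 0L; next }
    allowed <- allowed + if (el %in% c("N", "O", "P", "S")) s$formal[i] else -abs(s$formal[i])
    ok <- allowed[allowed >= bondsum[i]]
    target <- if (length(ok) > 0) min(ok) else max(allowed, bondsum[i])
    nH[i] <- max(0L, as.integer(round(target - bondsum[i])))
  }
  hyb <- map_chr(m$sybyl, function(ty) {
    suf <- sub("^[^.]+\\.?", "", ty)
    switch(suf,
      "1" = "sp", "2" = "sp2", "ar" = "sp2", "co2" = "sp2", "cat" = "sp2",
      "am" = "sp2", "sp3"
    )
  })
  obj <- structure(list(
    id = id,
    smiles = smiles,
    fragment = frag,
    cansmi = props$cansmi[[1]],
    atoms = tibble(
      element = s$element, sybyl = m$sybyl, hyb = hyb,
      formal = s$formal, charge = m$charge,
      degree = degree, nH = nH, aromatic = atom_aromatic
    ),
    bonds = mutate(bonds, aromatic = bond_aromatic, in_ring = in_ring),
    props = props
  ), class = "mol")
  .mol_cache[[smiles]] <- obj
  obj
}

#' @export
print.mol <- function(x, ...) {
  cat(sprintf("<mol %s: %d heavy atoms, %d bonds, %s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), x$cansmi))
  invisible(x)
}

# a bond is in a ring iff its endpoints stay connected after its removal
bond_in_ring <- function(n_atoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0) return(logical(0))
  out <- logical(nb)
  adj <- adjacency_list(n_atoms, bonds)
  for (i in seq_len(nb)) {
    s <- bonds$a1[i]; t <- bonds$a2[i]
    seen <- logical(n_atoms)
    seen[s] <- TRUE
    queue <- s
    found <- FALSE
    while (length(queue) > 0 && !found) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == s && w == t) next
        if (w == s && v == t) next
        if (!seen[w]) {
          if (w == t) { found <- TRUE; break }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out[i] <- found
  }
  out
}

adjacency_list <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) adj[[i]] <- integer(0)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
  }
  adj
}

# all simple paths with 1..max_len edges, each counted once
# returns a list of integer vectors (atom index sequences)
enumerate_paths <- function(n_atoms, bonds, max_len) {
  adj <- adjacency_list(n_atoms, bonds)
  paths <- list()
  extend <- function(path, visited) {
    v <- path[[length(path)]]
    for (w in adj[[v]]) {
      if (visited[w]) next
      new_path <- c(path, w)
      if (w > path[[1]]) paths[[length(paths) + 1L]] <<- new_path
      if (length(new_path) - 1L < max_len) {
        visited[w] <- TRUE
        extend(new_path, visited)
        visited[w] <- FALSE
      }
    }
  }
  for (v in seq_len(n_atoms)) {
    visited <- logical(n_atoms)
    visited[v] <- TRUE
    extend(v, visited)
  }
  paths
}

# simple cycles of length 3..max_len, each counted once
enumerate_rings <- function(n_atoms, bonds, max_len = 6) {
  adj <- adjacency_list(n_atoms, bonds)
  rings <- list()
  search <- function(path, visited) {
    v <- path[[length(path)]]
    start <- path[[1]]
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3) {
        # canonical: start is minimum, second < last
        if (path[[2]] < path[[length(path)]]) {
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!visited[w] && w > start && length(path) < max_len) {
        visited[w] <- TRUE
        search(c(path, w), visited)
        visited[w] <- FALSE
      }
    }
  }
  for (v in seq_len(n_atoms)) {
    visited <- logical(n_atoms)
    visited[v] <- TRUE
    search(v, visited)
  }
  rings
}
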