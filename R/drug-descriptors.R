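# Molecular descriptors: 30 constitutional + 23 connectivity + 6 property +
# 7 kappa + 12 charge + 166 MACCS keys + 79 E-state counts = 323.

CONST_NAMES <- c(
  "Weight", "AWeight", "nhyd", "nhal", "nhet", "nhev", "ncof", "ncocl",
  "ncobr", "ncoi", "ncarb", "nphos", "nsulph", "noxy", "nnitro", "nring",
  "nrot", "ndonr", "naccr", "nsb", "ndb", "ntb", "naro", "nta",
  "PC1", "PC2", "PC3", "PC4", "PC5", "PC6"
)
CONN_NAMES <- c(
  paste0("Chi", 0:10), "Chi3c", "Chi4c", "Chi4pc",
  paste0("Chi", 3:6, "ch"), paste0("Chiv", 0:4)
)
PROP_NAMES <- c("LogP", "LogP2", "MR", "TPSA", "Hy", "UI")
KAPPA_NAMES <- c("kappa1", "kappa2", "kappa3", "kappam1", "kappam2", "kappam3", "phi")
CHARGE_NAMES <- c(
  "Qmax", "Qmin", "Qpos", "Qneg", "Tac", "Mac", "Qass",
  "Rpc", "Rnc", "SPP", "LDI", "Qnet"
)

estate_types <- function() {
  if (is.null(.tables_env$estate)) {
    .tables_env$estate <- read_versioned_tsv("estate_atom_types.tsv",
      md5 = "1bb16af2b549aae550b6bb4a84a8a912")
  }
  .tables_env$estate$type
}

as_mol <- function(mol) {
  if (inherits(mol, "mol")) return(mol)
  if (is.character(mol) && length(mol) == 1) return(parse_ligand(mol, mol))
  abort("expected a 'mol' object or a SMILES string")
}

#' Constitutional descriptors (30)
#'
#' Element counts, bond-type counts, ring count (cyclomatic number),
#' rotatable-bond count, hydrogen-bond donor/acceptor counts, molecular
#' weight, and simple-path counts of lengths 1-6 on the hydrogen-depleted
#' graph. Undefined values on degenerate molecules are 0.
#'
#' @param mol A [parse_ligand()] object (or SMILES string).
#' @return Named numeric vector of length 30.
#' @export
constitutional_descriptors <- function(mol) {
  mol <- as_mol(mol)
  a <- mol$atoms; b <- mol$bonds
  nhev <- nrow(a)
  nhyd <- sum(a$nH)
  count_el <- function(el) sum(a$element == el)
  nring <- nrow(b) - nhev + n_components(nhev, b)
  rot <- b$order == 1 & !b$aromatic & !b$in_ring &
    a$degree[b$a1] >= 2 & a$degree[b$a2] >= 2
  paths <- enumerate_paths(nhev, b, max_len = 6)
  plen <- lengths(paths) - 1L
  pc <- map_dbl(1:6, function(k) sum(plen == k))
  mw <- mol$props$MW[[1]] %||% 0
  vals <- c(
    Weight = mw,
    AWeight = if (nhev + nhyd > 0) mw / (nhev + nhyd) else 0,
    nhyd = nhyd,
    nhal = sum(a$element %in% c("F", "Cl", "Br", "I")),
    nhet = nhev - count_el("C"),
    nhev = nhev,
    ncof = count_el("F"), ncocl = count_el("Cl"),
    ncobr = count_el("Br"), ncoi = count_el("I"),
    ncarb = count_el("C"), nphos = count_el("P"),
    nsulph = count_el("S"), noxy = count_el("O"), nnitro = count_el("N"),
    nring = nring,
    nrot = sum(rot),
    ndonr = mol$props$HBD[[1]] %||% 0,
    naccr = mol$props$HBA1[[1]] %||% 0,
    nsb = sum(b$order == 1 & !b$aromatic),
    ndb = sum(b$order == 2 & !b$aromatic),
    ntb = sum(b$order == 3),
    naro = sum(b$aromatic),
    nta = nhev + nhyd
  )
  out <- c(vals, setNames(pc, paste0("PC", 1:6)))
  setNames(out, paste0("const_", CONST_NAMES))
}

n_components <- function(n_atoms, bonds) {
  if (n_atoms == 0) return(0L)
  parent <- seq_len(n_atoms)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(bonds))) {
    r1 <- find(bonds$a1[i]); r2 <- find(bonds$a2[i])
    if (r1 != r2) parent[r1] <- r2
  }
  length(unique(map_dbl(seq_len(n_atoms), find)))
}

# simple delta: heavy-atom degree; valence delta: Kier-Hall
atom_deltas <- function(mol) {
  a <- mol$atoms
  zv <- unname(VALENCE_ELECTRONS[a$element])
  z <- unname(ATOMIC_NUMBER[a$element])
  dv <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (is.na(zv[i]) || is.na(z[i])) { dv[i] <- a$degree[i]; next }
    denom <- z[i] - zv[i] - 1
    dv[i] <- if (denom <= 1) zv[i] - a$nH[i] else (zv[i] - a$nH[i]) / denom
  }
  list(d = as.numeric(a$degree), dv = dv)
}

chi_term <- function(delta, atoms) {
  d <- delta[atoms]
  if (any(d <= 0)) return(0)
  1 / sqrt(prod(d))
}

#' Molecular connectivity indices (23)
#'
#' Kier-Hall chi indices: simple path chi of orders 0-10, cluster chi (3c,
#' 4c), path/cluster chi (4pc), chain (ring) chi of orders 3-6, and valence
#' path chi of orders 0-4. Atoms with zero heavy-atom degree contribute the
#' degenerate value 0.
#'
#' @inheritParams constitutional_descriptors
#' @return Named numeric vector of length 23.
#' @export
connectivity_indices <- function(mol) {
  mol <- as_mol(mol)
  n <- nrow(mol$atoms)
  deltas <- atom_deltas(mol)
  adj <- adjacency_list(n, mol$bonds)
  paths <- enumerate_paths(n, mol$bonds, max_len = 10)
  plen <- lengths(paths) - 1L
  chi_path <- function(delta, max_order) {
    out <- numeric(max_order + 1)
    out[1] <- sum(1 / sqrt(delta[delta > 0]))
    for (k in seq_len(max_order)) {
      sel <- paths[plen == k]
      out[k + 1] <- sum(map_dbl(sel, function(p) chi_term(delta, p)))
    }
    out
  }
  chi <- chi_path(deltas$d, 10)
  chiv <- chi_path(deltas$dv, 4)
  cluster_chi <- function(delta, size) {
    tot <- 0
    for (v in seq_len(n)) {
      nb <- adj[[v]]
      if (length(nb) < size) next
      for (comb in combn_list(nb, size)) {
        tot <- tot + chi_term(delta, c(v, comb))
      }
    }
    tot
  }
  chi3c <- cluster_chi(deltas$d, 3)
  chi4c <- cluster_chi(deltas$d, 4)
  chi4pc <- 0
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) < 3) next
    for (comb in combn_list(nb, 3)) {
      for (x in comb) {
        for (w in adj[[x]]) {
          if (w == v || w %in% comb) next
          chi4pc <- chi4pc + chi_term(deltas$d, c(v, comb, w))
        }
      }
    }
  }
  rings <- enumerate_rings(n, mol$bonds, max_len = 6)
  rlen <- lengths(rings)
  chich <- map_dbl(3:6, function(k) {
    sum(map_dbl(rings[rlen == k], function(r) chi_term(deltas$d, r)))
  })
  out <- c(chi, chi3c, chi4c, chi4pc, chich, chiv)
  setNames(out, paste0("conn_", CONN_NAMES))
}

combn_list <- function(x, m) {
  if (length(x) < m) return(list())
  cm <- utils::combn(x, m)
  lapply(seq_len(ncol(cm)), function(j) cm[, j])
}

#' Kappa shape indices (7)
#'
#' First to third order kappa shape indices, their alpha-modified variants
#' (Kier covalent-radius correction), and the flexibility index phi =
#' kappam1 * kappam2 / A. Degenerate molecules (no paths of the required
#' length) yield 0.
#'
#' @inheritParams constitutional_descriptors
#' @return Named numeric vector of length 7.
#' @export
kappa_shape <- function(mol) {
  mol <- as_mol(mol)
  a <- nrow(mol$atoms)
  paths <- enumerate_paths(a, mol$bonds, max_len = 3)
  plen <- lengths(paths) - 1L
  p1 <- sum(plen == 1); p2 <- sum(plen == 2); p3 <- sum(plen == 3)
  alpha <- sum(map_dbl(seq_len(a), function(i) {
    key <- paste0(mol$atoms$element[i], ".", mol$atoms$hyb[i])
    val <- unname(KIER_ALPHA[key])
    if (is.na(val)) 0 else val
  }))
  kap <- function(a_eff, p1e, p2e, p3e) {
    k1 <- if (p1e > 0) a_eff * (a_eff - 1)^2 / p1e^2 else 0
    k2 <- if (p2e > 0) (a_eff - 1) * (a_eff - 2)^2 / p2e^2 else 0
    k3 <- if (p3e > 0) {
      if (round(a_eff) %% 2 == 1) (a_eff - 1) * (a_eff - 3)^2 / p3e^2
      else (a_eff - 3) * (a_eff - 2)^2 / p3e^2
    } else 0
    c(k1, k2, k3)
  }
  k <- kap(a, p1, p2, p3)
  km <- kap(a + alpha, p1 + alpha, p2 + alpha, p3 + alpha)
  phi <- if (a > 0) km[1] * km[2] / a else 0
  setNames(c(k, km, phi), paste0("kappa_", KAPPA_NAMES))
}

#' Whole-molecule charge descriptors (12)
#'
#' Summary statistics of Gasteiger partial charges on the heavy-atom graph:
#' extreme charges, positive/negative/total/absolute sums and means, sum of
#' squares, relative positive/negative charge, submolecular polarity
#' parameter (Qmax - Qmin), local dipole index (mean absolute charge
#' difference over bonds), and net formal charge. Degenerate values are 0.
#'
#' @inheritParams constitutional_descriptors
#' @return Named numeric vector of length 12.
#' @export
charge_descriptors <- function(mol) {
  mol <- as_mol(mol)
  q <- mol$atoms$charge
  b <- mol$bonds
  qpos <- sum(q[q > 0]); qneg <- sum(q[q < 0])
  ldi <- if (nrow(b) > 0) mean(abs(q[b$a1] - q[b$a2])) else 0
  vals <- c(
    Qmax = if (length(q)) max(q) else 0,
    Qmin = if (length(q)) min(q) else 0,
    Qpos = qpos,
    Qneg = qneg,
    Tac = sum(abs(q)),
    Mac = if (length(q)) mean(abs(q)) else 0,
    Qass = sum(q^2),
    Rpc = if (qpos > 0) max(q) / qpos else 0,
    Rnc = if (qneg < 0) min(q) / qneg else 0,
    SPP = if (length(q)) max(q) - min(q) else 0,
    LDI = ldi,
    Qnet = sum(mol$atoms$formal)
  )
  setNames(vals, paste0("charge_", CHARGE_NAMES))
}

#' Molecular property descriptors (6)
#'
#' Wildman-Crippen logP (and its square) and molar refractivity MR, and
#' topological polar surface area TPSA (all from OpenBabel), plus the
#' hydrophilic factor Hy and the unsaturation index
#' UI = log2(1 + ndb + ntb + naro).
#'
#' @inheritParams constitutional_descriptors
#' @return Named numeric vector of length 6.
#' @export
molecular_properties <- function(mol) {
  mol <- as_mol(mol)
  a <- mol$atoms; b <- mol$bonds
  logp <- mol$props$logP[[1]] %||% 0
  mr <- mol$props$MR[[1]] %||% 0
  tpsa <- mol$props$TPSA[[1]] %||% 0
  nheavy <- nrow(a)
  n_hy <- sum(a$nH[a$element %in% c("N", "O", "S")])
  nc <- sum(a$element == "C")
  hy <- if (nheavy >= 1) {
    ((1 + n_hy) * log2(1 + n_hy) + nc * (1 / nheavy) * log2(1 / nheavy) +
       sqrt(n_hy / nheavy^2)) / log2(1 + nheavy)
  } else 0
  u <- sum(b$order == 2 & !b$aromatic) + sum(b$order == 3) + sum(b$aromatic)
  vals <- c(LogP = logp, LogP2 = logp^2, MR = mr, TPSA = tpsa,
            Hy = hy, UI = log2(1 + u))
  setNames(vals, paste0("prop_", PROP_NAMES))
}

#' MACCS substructure keys (166 binary values)
#'
#' The 166-key Molecular Access System dictionary, computed by OpenBabel;
#' position k holds key k.
#'
#' @inheritParams constitutional_descriptors
#' @return Named 0/1 numeric vector of length 166.
#' @export
maccs_keys <- function(mol) {
  mol <- as_mol(mol)
  fp <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", mol$fragment, identity), "MACCS"
  )
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  bits <- as.numeric(fp[1, 1:166] != 0)
  setNames(bits, sprintf("maccs_%03d", 1:166))
}

#' E-state fingerprint (79 atom-type counts)
#'
#' Occurrence counts over the 79 Kier-Hall electrotopological atom types.
#' Each heavy atom is typed from its element, implicit hydrogen count and the
#' bond orders to its heavy neighbors (s/d/t per single/double/triple bond,
#' `aa` for aromatic pairs). Atoms matching no type (e.g. an unbonded carbon,
#' or elements outside the dictionary) are left uncounted.
#'
#' @inheritParams constitutional_descriptors
#' @return Named nonnegative integer vector of length 79.
#' @export
estate_fingerprint <- function(mol) {
  mol <- as_mol(mol)
  types <- estate_types()
  counts <- setNames(numeric(length(types)), types)
  a <- mol$atoms; b <- mol$bonds
  for (i in seq_len(nrow(a))) {
    sym <- character(0)
    sel <- which(b$a1 == i | b$a2 == i)
    for (j in sel) {
      sym <- c(sym, if (b$aromatic[j] || b$order[j] >= 4) "a" else
        switch(b$order[j], "s", "d", "t"))
    }
    # canonical symbol order: aromatic, triple, double, single
    sym <- sym[order(match(sym, c("a", "t", "d", "s")))]
    h <- a$nH[i]
    hs <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
    name <- paste0(paste(sym, collapse = ""), a$element[i], hs)
    if (!name %in% types && a$element[i] == "As") name <- "sssdAs"
    if (name %in% types) counts[name] <- counts[name] + 1
  }
  setNames(counts, paste0("estate_", types))
}

#' Full drug feature block (323 descriptors)
#'
#' Concatenation, in fixed order, of constitutional (30), connectivity (23),
#' molecular property (6), kappa shape (7), charge (12), MACCS key (166) and
#' E-state fingerprint (79) blocks.
#'
#' @param smiles SMILES string (salts reduce to the largest fragment) or a
#'   [parse_ligand()] object.
#' @param id Ligand identifier used in messages.
#' @return Named numeric vector of length 323.
#' @export
#' @examples
#' length(drug_features("CCO"))
drug_features <- function(smiles, id = "ligand") {
  mol <- if (inherits(smiles, "mol")) smiles else parse_ligand(id, smiles)
  out <- c(
    constitutional_descriptors(mol),
    connectivity_indices(mol),
    molecular_properties(mol),
    kappa_shape(mol),
    charge_descriptors(mol),
    maccs_keys(mol),
    estate_fingerprint(mol)
  )
  stopifnot(length(out) == 323)
  out
}

#' The 755-name feature manifest
#'
#' Ordered descriptor names for one encoded drug-target pair: 432 protein
#' descriptors (blocks `aac`, `moran`, `ctd`) followed by 323 drug descriptors
#' (blocks `const`, `conn`, `prop`, `kappa`, `charge`, `maccs`, `estate`).
#' The order is contractual: trained models store it and refuse mismatched
#' feature matrices.
#'
#' @return A tibble with columns `index`, `block`, `name`.
#' @export
feature_manifest <- function() {
  if (!is.null(.tables_env$manifest)) return(.tables_env$manifest)
  prot <- protein_features(strrep("ACDEFGHIKLMNPQRSTVWY", 3))
  drug <- drug_features("CCO")
  nm <- c(names(prot), names(drug))
  out <- tibble(
    index = seq_along(nm),
    block = sub("_.*$", "", nm),
    name = nm
  )
  .tables_env$manifest <- out
  out
}
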