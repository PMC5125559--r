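rec <- function(d, t, label = "positive", source = "A", bio = NA_real_) {
  tibble::tibble(drug_id = d, target_id = t, label = label, source = source,
                 bioactivity_um = bio)
}

test_that("deduplication keeps one record per key, earliest source first", {
  x <- dplyr::bind_rows(rec("d1", "t1", source = "A"), rec("d1", "t1", source = "B"))
  out <- dedup_interactions(x, set_order = c("A", "B"))
  expect_equal(nrow(out), 1)
  expect_equal(out$source, "A")

  # source order respected even when listed later in the table
  y <- dplyr::bind_rows(rec("d1", "t1", source = "B"), rec("d1", "t1", source = "A"))
  out2 <- dedup_interactions(y, set_order = c("A", "B"))
  expect_equal(out2$source, "A")
})

test_that("label conflicts resolve to positive with a message", {
  x <- dplyr::bind_rows(rec("d1", "t1", "positive", "A"),
                        rec("d1", "t1", "negative", "B"))
  expect_message(out <- dedup_interactions(x), "conflict")
  expect_equal(nrow(out), 1)
  expect_equal(out$label, "positive")
  # same outcome when the negative is seen first
  y <- dplyr::bind_rows(rec("d1", "t1", "negative", "B"),
                        rec("d1", "t1", "positive", "A"))
  expect_message(out2 <- dedup_interactions(y), "conflict")
  expect_equal(out2$label, "positive")
})

test_that("planted duplicates are removed and dedup is idempotent", {
  base <- rec(sprintf("d%02d", 1:80), sprintf("t%02d", 1:80))
  dup_idx <- withr::with_seed(5, sample(80, 20))
  x <- dplyr::bind_rows(base, base[dup_idx, ])
  out <- dedup_interactions(x)
  expect_equal(nrow(out), 80)
  expect_equal(dedup_interactions(out), out)
})

test_that("weak-binder extraction is strictly greater than the threshold", {
  x <- rec(paste0("d", 1:4), paste0("t", 1:4), bio = c(0.1, 10.0, 10.1, 500))
  out <- filter_weak_binders(x)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$bioactivity_um), c(10.1, 500))
  expect_true(all(out$label == "negative"))
  expect_equal(nrow(filter_weak_binders(rec("d", "t", bio = 10.0))), 0)
})

test_that("bioactivity units convert to micromolar before comparison", {
  x <- rec(paste0("d", 1:3), paste0("t", 1:3), bio = c(9000, 11000, 0.02))
  x$bioactivity_unit <- c("nM", "nM", "mM")
  out <- filter_weak_binders(x)
  # 9000 nM = 9 uM (kept out), 11000 nM = 11 uM, 0.02 mM = 20 uM
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$bioactivity_um), c(11, 20))
})

test_that("records without bioactivity are skipped with a message", {
  x <- rec(paste0("d", 1:2), paste0("t", 1:2), bio = c(NA, 50))
  expect_message(out <- filter_weak_binders(x), "skipped")
  expect_equal(nrow(out), 1)
})

test_that("Tanimoto similarity matches hand computation", {
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(tanimoto_similarity(c(1, 1, 1, 0), c(1, 1, 0, 1)), 0.5)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  expect_equal(tanimoto_similarity(c(0, 0), c(0, 0)), 0.0)
})

test_that("redundancy report flags identical ligands and handles tiny input", {
  same <- tibble::tibble(id = c("a", "b"), smiles = c("CCO", "OCC"))
  r <- fingerprint_redundancy_report(same)
  expect_equal(r$n_pairs, 1L)
  expect_equal(r$fraction_above, 1.0)

  one <- fingerprint_redundancy_report(same[1, ])
  expect_equal(one$n_pairs, 0L)
  expect_equal(one$fraction_above, 0)

  mixed <- fingerprint_redundancy_report(fixture_ligands()[1:6, ])
  expect_equal(mixed$n_pairs, 15L)
  expect_lt(mixed$fraction_above, 1)
})

test_that("negative allocation follows the round(ratio x n) quota rule", {
  pos <- list(rec(paste0("a", 1:4), paste0("x", 1:4)),
              rec(paste0("b", 1:2), paste0("y", 1:2)))
  pool <- rec(paste0("n", 1:9), paste0("z", 1:9), label = "negative")
  out <- allocate_negatives(pos, pool, ratio = 1.5, seed = 3)
  expect_equal(vapply(out, nrow, integer(1)), c(4L + 6L, 2L + 3L))

  expect_warning(empty <- allocate_negatives(pos, pool[0, ], ratio = 1.5, seed = 3),
                 "proportional")
  expect_equal(vapply(empty, nrow, integer(1)), c(4L, 2L))
})

test_that("an explicit override reproduces published split sizes", {
  pos <- list(
    train = rec(sprintf("yp%05d", 1:7206), sprintf("yt%05d", 1:7206), source = "yamanishi"),
    external = rec(sprintf("dp%05d", 1:3530), sprintf("dt%05d", 1:3530), source = "drugbank")
  )
  pool <- rec(sprintf("np%05d", 1:16209), sprintf("nt%05d", 1:16209),
              label = "negative", source = "bindingdb")
  out <- allocate_negatives(pos, pool, seed = 17, override = c(10912L, 5297L))
  expect_equal(nrow(out$train), 18118)
  expect_equal(nrow(out$external), 8827)
  keys <- function(x) paste(x$drug_id, x$target_id)
  expect_equal(length(intersect(keys(out$train), keys(out$external))), 0)
})

test_that("allocation conserves the pool and is disjoint across fuzzed configs", {
  for (seed in 1:50) {
    sizes <- withr::with_seed(seed, sample(1:30, 3))
    pool_n <- withr::with_seed(seed + 1, sample(20:120, 1))
    pos <- purrr::imap(sizes, function(n, i) {
      rec(sprintf("s%d_d%d", i, 1:n), sprintf("s%d_t%d", i, 1:n))
    })
    pool <- rec(sprintf("pool_d%d", 1:pool_n), sprintf("pool_t%d", 1:pool_n),
                label = "negative")
    out <- suppressWarnings(allocate_negatives(pos, pool, ratio = 1.5, seed = seed))
    negs <- purrr::map(out, function(x) x[x$label == "negative", ])
    expect_equal(sum(vapply(negs, nrow, integer(1))), pool_n)
    all_keys <- unlist(purrr::map(negs, function(x) paste(x$drug_id, x$target_id)))
    expect_false(any(duplicated(all_keys)))
  }
})

test_that("allocation is seed-stable and seed-sensitive at fixed sizes", {
  pos <- list(rec(paste0("a", 1:6), paste0("x", 1:6)),
              rec(paste0("b", 1:4), paste0("y", 1:4)))
  pool <- rec(paste0("n", 1:15), paste0("z", 1:15), label = "negative")
  a <- allocate_negatives(pos, pool, seed = 1)
  b <- allocate_negatives(pos, pool, seed = 1)
  c <- allocate_negatives(pos, pool, seed = 2)
  expect_identical(a, b)
  expect_equal(vapply(a, nrow, integer(1)), vapply(c, nrow, integer(1)))
  expect_false(identical(a, c))
})

test_that("overlapping pool and positives are rejected", {
  pos <- list(rec("d1", "t1"))
  pool <- rec("d1", "t1", label = "negative")
  expect_error(allocate_negatives(pos, pool), "overlaps")
})

test_that("encoding assembles 755-wide rows with per-entity caching", {
  prots <- random_proteins(2, length = 40, seed = 31)
  ligs <- fixture_ligands()[1:2, ]
  recs <- tibble::tibble(
    drug_id = c(ligs$id[1], ligs$id[2], ligs$id[1]),
    target_id = c(prots$id[1], prots$id[1], prots$id[2]),
    label = c("positive", "negative", "positive")
  )
  ds <- encode_dataset(recs, prots, ligs)
  expect_equal(dim(ds$features), c(3, 755))
  expect_equal(attr(ds, "n_featurizations"), 4L)
  expect_equal(ds$labels, c(1L, 0L, 1L))
  expect_equal(colnames(ds$features), feature_manifest()$name)

  empty <- encode_dataset(recs[0, ], prots, ligs)
  expect_equal(nrow(empty$features), 0)
})

test_that("records with unknown entities are dropped with a message", {
  prots <- random_proteins(1, length = 40, seed = 32)
  ligs <- fixture_ligands()[1, ]
  recs <- tibble::tibble(
    drug_id = c(ligs$id, "missing_drug"),
    target_id = c(prots$id, prots$id),
    label = "positive"
  )
  expect_message(ds <- encode_dataset(recs, prots, ligs), "dropped 1")
  expect_equal(nrow(ds$features), 1)
})

test_that("interaction TSV reader and writer round-trip", {
  x <- rec(paste0("d", 1:3), paste0("t", 1:3), bio = c(1, 20, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(x, path)
  back <- read_interactions(path)
  expect_equal(back$drug_id, x$drug_id)
  expect_equal(back$bioactivity_um, x$bioactivity_um)
})
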