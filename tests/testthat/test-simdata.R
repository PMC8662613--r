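test_that("simulate_taxonomy: shape, conservation, determinism", {
  sp <- simulate_taxonomy(2, seed = 1)
  expect_equal(length(sp$leaves), 2L)
  expect_equal(nrow(sp$taxonomy$nodes), 3L)
  for (n in c(5, 16, 33)) {
    sp <- simulate_taxonomy(n, seed = n)
    expect_equal(length(sp$leaves), n)
    expect_setequal(sp$leaves, taxonomy_leaves(sp$taxonomy))
  }
  a <- simulate_taxonomy(12, seed = 99)
  b <- simulate_taxonomy(12, seed = 99)
  expect_identical(a, b)
})

test_that("simulate_family: delta=0 gives one gene per species, all one2one", {
  sp <- simulate_taxonomy(7, seed = 2)
  set.seed(3)
  fam <- simulate_family(sp, dup_rate = 0, loss_rate = 0)
  expect_equal(sort(fam$leaves$species), sort(sp$leaves))
  expect_true(all(fam$nodes$type %in% c("S", "leaf")))
  rel <- family_orthologs(fam)
  expect_equal(nrow(rel), choose(7, 2))
  # an impossible regime errors rather than spinning
  expect_error(simulate_family(sp, dup_rate = 0, loss_rate = 50,
                               max_tries = 50),
               "rejection rate")
})

test_that("true orthology equals the per-pair LCA-walk oracle with types", {
  sp <- simulate_taxonomy(6, seed = 5)
  set.seed(6)
  for (rep in 1:20) {
    fam <- simulate_family(sp, dup_rate = 0.5, loss_rate = 0.1)
    rel <- family_orthologs(fam)
    keys <- paste(rel$protein_a, rel$protein_b)
    ids <- fam$leaves$leaf_id
    for (a in ids) for (b in ids) {
      if (a >= b) next
      is_orth <- gene_lca_type(fam, a, b) == "S"
      expect_equal(paste(min(a, b), max(a, b)) %in% keys, is_orth)
    }
    # a forced duplication at the root: cross-clade pairs are paralogs
    # (covered implicitly when the root node is D)
    if (fam$nodes$type[1] == "D") {
      kids <- which(fam$nodes$parent == 1L)
      under <- function(k) {
        out <- k
        repeat {
          nxt <- fam$nodes$id[fam$nodes$parent %in% out & !fam$nodes$id %in% out]
          if (!length(nxt)) break
          out <- c(out, nxt)
        }
        fam$leaves$leaf_id[fam$leaves$node_id %in% out]
      }
      l1 <- under(kids[1]); l2 <- under(kids[2])
      for (x in l1) for (y in l2)
        expect_false(paste(min(x, y), max(x, y)) %in% keys)
    }
  }
})

test_that("type counting on the true relation is consistent with classify_type", {
  # route 1: simdata counting rule; route 2: db-backed classify_type
  bm <- small_benchmark()
  db <- bm$db
  checked <- 0L
  for (f in bm$families) {
    rel <- f$orthologs
    both <- rel$protein_a %in% db$proteins$protein_id &
            rel$protein_b %in% db$proteins$protein_id
    rel_db <- rel[both, , drop = FALSE]
    if (!nrow(rel_db)) next
    for (i in seq_len(min(4L, nrow(rel_db)))) {
      a <- rel_db$protein_a[i]; b <- rel_db$protein_b[i]
      og <- ogs_of(db, a)
      og <- og$og_id[og$level == db$taxonomy$root]
      if (!length(og)) next
      # family-wide scope and full-family relation agree in the db world
      # restricted to db members
      fam_db <- f$family
      keep <- fam_db$leaves$leaf_id %in% db$proteins$protein_id
      fam_res <- list(nodes = fam_db$nodes,
                      leaves = fam_db$leaves[keep, , drop = FALSE])
      class(fam_res) <- "sim_family"
      expect_equal(classify_type(db, a, b, og),
                   family_pair_type(fam_res, rel_db, a, b))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("evolve_sequences: r=0 identity, divergence matches closed form", {
  sp <- simulate_taxonomy(4, seed = 7)
  set.seed(8)
  fam <- simulate_family(sp, 0, 0)
  ev0 <- evolve_sequences(fam, root_length = 100, r = 0)
  expect_true(all(ev0$sequences == ev0$root))

  # two-leaf family at known distance: P(diff) = (1 - e^(-rT)) * 19/20
  nodes <- data.frame(id = 1:3, parent = c(0L, 1L, 1L),
                      type = c("S", "leaf", "leaf"), species = c(1L, 2L, 3L),
                      brlen = c(0, 0.25, 0.25))
  leaves <- data.frame(leaf_id = c("a", "b"), node_id = 2:3,
                       species = 2:3)
  fam2 <- structure(list(nodes = nodes, leaves = leaves),
                    class = "sim_family")
  L <- 3000L
  ev <- evolve_sequences(fam2, root_length = L, r = 1, seed = 9)
  d <- mean(strsplit(ev$sequences[["a"]], "")[[1]] !=
            strsplit(ev$sequences[["b"]], "")[[1]])
  T_ <- 0.5
  p <- (1 - exp(-T_)) * 19 / 20
  # within 3 sigma of the binomial expectation
  expect_lt(abs(d - p), 3 * sqrt(p * (1 - p) / L) + 0.01)

  ev_a <- evolve_sequences(fam2, root_length = 50, r = 1, seed = 10)
  ev_b <- evolve_sequences(fam2, root_length = 50, r = 1, seed = 10)
  expect_identical(ev_a, ev_b)
})

test_that("assign_functions: p=0 inert, p=1 forced swap, ortholog Jaccard wins", {
  sp <- simulate_taxonomy(6, seed = 11)
  set.seed(12)
  fam <- simulate_family(sp, 0.4, 0.1)
  base <- sprintf("GO:%07d", 1:8)
  f0 <- assign_functions(fam, base, p = 0)
  for (ts in f0$terms) expect_setequal(ts, base)

  # p=1, one duplication: the two clades differ by exactly the swapped half
  nodes <- data.frame(id = 1:3, parent = c(0L, 1L, 1L),
                      type = c("D", "leaf", "leaf"),
                      species = c(NA, 2L, 3L), brlen = c(0, .1, .1))
  leaves <- data.frame(leaf_id = c("a", "b"), node_id = 2:3, species = 2:3)
  fam1 <- structure(list(nodes = nodes, leaves = leaves),
                    class = "sim_family")
  f1 <- assign_functions(fam1, base, p = 1, seed = 13)
  shared <- intersect(f1$terms[["a"]], f1$terms[["b"]])
  expect_equal(length(shared), 4L)
  expect_equal(length(setdiff(union(f1$terms[["a"]], f1$terms[["b"]]),
                              shared)), 8L)

  # across families: term Jaccard of true orthologs >= paralog pairs
  set.seed(14)
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  j_orth <- c(); j_par <- c()
  for (rep in 1:25) {
    fam <- simulate_family(sp, 0.5, 0.05)
    fn <- assign_functions(fam, base, p = 0.8)
    rel <- family_orthologs(fam)
    keys <- paste(rel$protein_a, rel$protein_b)
    ids <- fam$leaves$leaf_id
    for (a in ids) for (b in ids) {
      if (a >= b) next
      j <- jac(fn$terms[[a]], fn$terms[[b]])
      if (paste(a, b) %in% keys) j_orth <- c(j_orth, j)
      else j_par <- c(j_par, j)
    }
  }
  expect_gte(mean(j_orth), mean(j_par))
})

test_that("emit_benchmark is deterministic and every query has truth rows", {
  p <- sim_params(n_species = 6L, n_families = 6L, root_length = 80L,
                  seed = 15L)
  a <- emit_benchmark(p)
  b <- emit_benchmark(p)
  expect_identical(a$queries, b$queries)
  expect_identical(a$key, b$key)
  expect_true(isTRUE(db_equal(a$db, b$db)))
  expect_setequal(a$key$query, names(a$queries))
  # lossless world: every query keeps at least one database ortholog
  p0 <- sim_params(n_species = 6L, n_families = 6L, root_length = 80L,
                   loss_rate = 0, seed = 16L)
  bm0 <- emit_benchmark(p0)
  expect_true(all(nzchar(bm0$key$true_orthologs)))
})
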