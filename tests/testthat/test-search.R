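scheme <- default_scoring()

test_that("k-mer index covers every substring and agrees with naive scan", {
  tx <- toy_taxonomy()
  db <- ref_db(tx, proteins = data.frame(
    protein_id = "P1", tax_id = 3L, sequence = "MKV",
    stringsAsFactors = FALSE))
  idx <- build_kmer_index(db, 2)
  expect_setequal(idx$dt$kmer, c("MK", "KV"))

  set.seed(41)
  seqs <- vapply(1:6, function(i) random_protein(sample(20:60, 1)),
                 character(1))
  db <- ref_db(tx, proteins = data.frame(
    protein_id = paste0("P", 1:6), tax_id = 3L, sequence = seqs,
    stringsAsFactors = FALSE))
  k <- 3
  idx <- build_kmer_index(db, k)
  # conservation: total postings = sum(len - k + 1)
  expect_equal(nrow(idx$dt), sum(nchar(seqs) - k + 1L))
  # agreement with a naive substring scan
  for (rep in 1:20) {
    kmer <- substring(seqs[sample(6, 1)], s <- sample(1:18, 1), s + k - 1L)
    got <- kmer_lookup(idx, kmer)
    for (i in seq_along(seqs)) {
      naive <- which(vapply(seq_len(nchar(seqs[i]) - k + 1L), function(p)
        substring(seqs[i], p, p + k - 1L) == kmer, logical(1)))
      expect_setequal(got[got$target == paste0("P", i)]$pos, naive)
    }
  }
})

test_that("smith_waterman: self-alignment, textbook pair, empty alignment", {
  s <- "MKVLAWGHED"
  h <- smith_waterman(s, s, scheme)
  diag_sum <- sum(diag(scheme$matrix[strsplit(s, "")[[1]],
                                     strsplit(s, "")[[1]]]))
  expect_equal(h$raw_score, diag_sum)
  expect_equal(h$percent_identity, 100)
  expect_equal(h$aligned_pairs[, 1], h$aligned_pairs[, 2])

  h2 <- smith_waterman("HEAGAWGHEE", "PAWHEAE", scheme)
  expect_equal(h2$raw_score,
               sw_oracle("HEAGAWGHEE", "PAWHEAE", scheme$matrix))
  # raw score equals re-scoring the traceback
  expect_equal(h2$raw_score, rescore_traceback(h2, "HEAGAWGHEE", "PAWHEAE",
                                               scheme))

  # disjoint alphabets, all-negative: empty alignment, score 0
  h3 <- smith_waterman("WWWWW", "PPPPP", scheme)
  expect_equal(h3$raw_score, 0)
  expect_equal(nrow(h3$aligned_pairs), 0L)

  expect_error(smith_waterman("MK1", "MK", scheme), "outside")
})

test_that("smith_waterman equals the full-DP oracle on random pairs", {
  set.seed(53)
  for (rep in 1:40) {
    q <- random_protein(sample(20:60, 1))
    t <- random_protein(sample(20:60, 1))
    h <- smith_waterman(q, t, scheme)
    expect_equal(h$raw_score, sw_oracle(q, t, scheme$matrix))
    # symmetry of the optimal score
    expect_equal(smith_waterman(t, q, scheme)$raw_score, h$raw_score)
    # aligned pairs strictly increasing, score reproducible from traceback
    if (nrow(h$aligned_pairs) > 1) {
      expect_true(all(diff(h$aligned_pairs[, 1]) > 0))
      expect_true(all(diff(h$aligned_pairs[, 2]) > 0))
    }
    expect_equal(rescore_traceback(h, q, t, scheme), h$raw_score)
  }
})

test_that("E-value is monotone decreasing in raw score", {
  ev <- function(s) scheme$K * 100 * scheme$search_space *
    exp(-scheme$lambda * s)
  scores <- seq(10, 300, by = 10)
  expect_true(all(diff(ev(scores)) < 0))
  h <- smith_waterman("MKVLAWGHED", "MKVLAWGHED", scheme)
  expect_equal(h$bit_score,
               (scheme$lambda * h$raw_score - log(scheme$K)) / log(2))
})

test_that("search ranks an identical reference first; all-X is unmatched", {
  bm <- small_benchmark()
  db <- bm$db
  pid <- db$proteins$protein_id[5]
  qs <- c(exact = db$proteins$sequence[5],
          junk = strrep("X", 80))
  res <- search(qs, db, search_params("fast"))
  expect_equal(res$hits$exact[[1]]$target_id, pid)
  expect_equal(res$unmatched, "junk")
})

test_that("best_seed_ortholog tie-breaking is total and oracle-checked", {
  mk_hit <- function(t, ev, bs) structure(
    list(query_id = "q", target_id = t, raw_score = 0, bit_score = bs,
         evalue = ev, query_start = 1, query_end = 1, target_start = 1,
         target_end = 1, aligned_pairs = cbind(1, 1),
         percent_identity = 100), class = "alignment_hit")
  hits <- list(mk_hit("B", 1e-5, 50), mk_hit("A", 1e-5, 50),
               mk_hit("C", 1e-5, 60), mk_hit("D", 1e-7, 20))
  sorted <- orthomapper:::.sort_hits(hits)
  # evalue first, then bit score, then lexicographic target
  expect_equal(vapply(sorted, `[[`, character(1), "target_id"),
               c("D", "C", "A", "B"))
  expect_equal(best_seed_ortholog(sorted)$target_id, "D")
  # oracle: exhaustive re-sort
  ev <- sapply(hits, `[[`, "evalue"); bs <- sapply(hits, `[[`, "bit_score")
  tg <- sapply(hits, `[[`, "target_id")
  expect_equal(best_seed_ortholog(sorted)$target_id,
               tg[order(ev, -bs, tg)][1])
  expect_null(best_seed_ortholog(list()))
})

test_that("sensitive preset matches a superset of fast; iterative chains", {
  bm <- small_benchmark()
  qs <- bm$queries
  r_fast <- search(qs, bm$db, search_params("fast"))
  r_sens <- search(qs, bm$db, search_params("sensitive"))
  r_iter <- search(qs, bm$db, search_params("iterative"))
  matched <- function(r) setdiff(names(r$hits), r$unmatched)
  expect_true(all(matched(r_fast) %in% matched(r_sens)))
  # every fast-matched query keeps its fast hit under iterative
  for (q in matched(r_fast))
    expect_equal(r_iter$hits[[q]][[1]]$target_id,
                 r_fast$hits[[q]][[1]]$target_id)
  # iterative matches exactly fast + sensitive-rescued queries
  expect_setequal(matched(r_iter),
                  union(matched(r_fast),
                        intersect(matched(r_sens), names(qs))))
})

test_that("blastx recovers a back-translated reference on both strands", {
  bm <- small_benchmark()
  db <- bm$db
  pid <- db$proteins$protein_id[1]
  prot <- db$proteins$sequence[1]
  set.seed(9)
  nuc <- reverse_translate(prot)
  prot_hit <- search(setNames(prot, "q"), db)$hits$q[[1]]
  res <- blastx_search(c(fwd = nuc, rev = revcomp(nuc)), db)
  expect_equal(res$hits$fwd[[1]]$target_id, pid)
  expect_equal(res$hits$fwd[[1]]$frame, "+1")
  expect_equal(res$hits$fwd[[1]]$raw_score, prot_hit$raw_score)
  expect_equal(res$hits$rev[[1]]$target_id, pid)
  expect_equal(res$hits$rev[[1]]$frame, "-1")
  # too-short nucleotide input is unmatched, not an error
  short <- blastx_search(c(s = "ATGAAA"), db)
  expect_equal(short$unmatched, "s")
})

test_that("simulated 150 nt in-frame reads recover their source protein", {
  bm <- small_benchmark()
  db <- bm$db
  set.seed(77)
  picks <- sample(nrow(db$proteins), 40)
  prots <- setNames(db$proteins$sequence[picks],
                    db$proteins$protein_id[picks])
  rd <- sim_reads(prots, n = 40, read_len = 150, seed = 78)
  res <- blastx_search(rd$reads, db, search_params("fast"))
  top <- vapply(names(rd$reads), function(r) {
    h <- best_seed_ortholog(res$hits[[r]])
    if (is.null(h)) "" else h$target_id
  }, character(1))
  expect_gte(mean(top == rd$truth), 0.9)
})

test_that("hits table writes in the conventional 12-column dialect", {
  bm <- small_benchmark()
  qs <- bm$queries[1]
  res <- search(qs, bm$db)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(res, f)
  tab <- read.delim(f, header = FALSE)
  expect_equal(ncol(tab), 12L)
  expect_equal(tab[1, 1], names(qs))
})
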