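mk_hit <- function(qpos, tpos, q = "q", t = "t") structure(
  list(query_id = q, target_id = t, raw_score = 0, bit_score = 100,
       evalue = 0, query_start = min(qpos), query_end = max(qpos),
       target_start = min(tpos), target_end = max(tpos),
       aligned_pairs = cbind(query_pos = qpos, target_pos = tpos),
       percent_identity = 100), class = "alignment_hit")

test_that("map_coordinates: identity, outside, gap snapping, oracle", {
  # identical sequences: identity mapping
  h <- mk_hit(1:20, 1:20)
  expect_equal(map_coordinates(h, c(5, 12)), c(5, 12))
  # interval entirely upstream of the aligned region
  h2 <- mk_hit(11:20, 31:40)
  expect_null(map_coordinates(h2, c(1, 20)))
  # endpoints in gaps snap inward
  h3 <- mk_hit(c(1, 2, 3, 10, 11), c(5, 6, 7, 8, 9))
  expect_equal(map_coordinates(h3, c(6, 8)), c(2, 10))

  # random gapped alignments vs a per-column walk oracle
  set.seed(13)
  for (rep in 1:25) {
    qp <- sort(sample(1:60, 20)); tp <- sort(sample(1:60, 20))
    h <- mk_hit(qp, tp)
    s <- sample(1:60, 1); e <- min(60, s + sample(0:20, 1))
    walk <- which(tp >= s & tp <= e)
    want <- if (length(walk)) c(qp[min(walk)], qp[max(walk)]) else NULL
    got <- map_coordinates(h, c(s, e))
    # oracle: first/last aligned column inside the interval; when the
    # interval covers only a gap the contract returns nothing
    if (is.null(want)) {
      if (!is.null(got)) expect_true(got[1] > got[2]) # cannot happen
      expect_null(got)
    } else expect_equal(got, want)
  }
})

test_that("pssm_score finds planted motifs and matches the brute oracle", {
  set.seed(17)
  motif <- random_protein(12)
  m <- toy_model(motif)
  win <- paste0(random_protein(20), motif, random_protein(15))
  r <- pssm_score(win, m)
  expect_equal(r$score, 5 * 12)            # self-score
  expect_equal(c(r$start, r$end), c(21, 32))

  # all-mismatch window scores <= 0
  wneg <- strrep(setdiff(c("A", "C"), strsplit(motif, "")[[1]])[1], 30)
  expect_lte(pssm_score(wneg, m)$score, 0)

  # brute-force offset oracle incl. edge truncation
  for (rep in 1:20) {
    w <- random_protein(sample(5:40, 1))
    mm <- toy_model(random_protein(sample(4:15, 1)))
    got <- pssm_score(w, mm)
    want <- pssm_oracle(w, mm)
    expect_equal(got$score, want$score)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("transfer/refine on planted domains; negatives are dropped", {
  bm <- small_benchmark()
  db <- bm$db
  planted <- bm$key[!is.na(bm$key$domain_model), ]
  negatives <- bm$key[is.na(bm$key$domain_model), ]
  expect_gt(nrow(planted), 0L)
  expect_gt(nrow(negatives), 0L)

  res <- annotate(bm$queries, db, domain_mode = "transfer")
  hits_checked <- 0L
  for (i in seq_len(nrow(planted))) {
    qid <- planted$query[i]
    dh <- res$domain_hits[res$domain_hits$query_id == qid, ]
    dh <- dh[dh$model_id == planted$domain_model[i], ]
    if (!nrow(dh)) next
    # indel-free world: transferred coordinates within +/-2 of truth
    expect_lte(abs(dh$start[1] - planted$domain_start[i]), 2)
    expect_lte(abs(dh$end[1] - planted$domain_end[i]), 2)
    hits_checked <- hits_checked + 1L
  }
  expect_gt(hits_checked, 0L)

  # spurious transfers onto negative-control sequences die at refinement
  some_model <- db$domain_models[[1]]
  for (qid in head(negatives$query, 5)) {
    qseq <- bm$queries[[qid]]
    fake <- data.frame(query_id = qid, model_id = some_model$model_id,
                       clan_id = some_model$clan_id, start = 10L,
                       end = 10L + some_model$length - 1L, score = 999,
                       mode = "transferred", stringsAsFactors = FALSE)
    expect_null(realign_refine(qseq, fake, db))
  }
  expect_error(realign_refine("MKV", data.frame(model_id = "nope"), db),
               "not present")
})

test_that("refinement only removes or adjusts; GA gate is absolute", {
  bm <- small_benchmark()
  res_t <- annotate(bm$queries, bm$db, domain_mode = "transfer")
  res_r <- annotate(bm$queries, bm$db, domain_mode = "refine")
  res_d <- annotate(bm$queries, bm$db, domain_mode = "denovo")
  # refinement never increases the per-query hit count
  for (qid in names(res_t$annotations)) {
    nt <- sum(res_t$domain_hits$query_id == qid)
    nr <- sum(res_r$domain_hits$query_id == qid)
    expect_lte(nr, nt)
  }
  # every refined/denovo hit satisfies its model's GA threshold
  for (d in list(res_r$domain_hits, res_d$domain_hits)) {
    if (!nrow(d)) next
    ga <- vapply(d$model_id, function(m)
      bm$db$domain_models[[m]]$ga_threshold, numeric(1))
    expect_true(all(d$score >= ga))
  }
})

test_that("empty model set gives an empty de novo scan", {
  db0 <- ref_db(toy_taxonomy(),
                proteins = data.frame(protein_id = "P3", tax_id = 3L,
                                      sequence = "MKVLAW"))
  expect_equal(nrow(denovo_scan("MKVLAW", db0)), 0L)
})

test_that("clan competition: contracts, idempotence, near-optimal greedy", {
  mk <- function(model, clan, s, e, sc)
    data.frame(query_id = "q", model_id = model, clan_id = clan,
               start = s, end = e, score = sc, mode = "denovo",
               stringsAsFactors = FALSE)
  # identical same-clan intervals: best score survives
  two <- rbind(mk("A", "CL1", 10, 40, 50), mk("B", "CL1", 10, 40, 60))
  kept <- clan_disambiguate(two)
  expect_equal(kept$model_id, "B")
  # different clans overlap freely
  two2 <- rbind(mk("A", "CL1", 10, 40, 50), mk("B", "CL2", 10, 40, 60))
  expect_equal(nrow(clan_disambiguate(two2)), 2L)
  # clan-less hits never compete
  two3 <- rbind(mk("A", "", 10, 40, 50), mk("B", "", 10, 40, 60))
  expect_equal(nrow(clan_disambiguate(two3)), 2L)

  # idempotence + greedy vs exhaustive subset oracle on random instances;
  # greedy is the contract, the oracle measures its optimality gap
  set.seed(29)
  mismatches <- 0L
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(1:80, 1)
      mk(sprintf("M%02d", i), sample(c("CL1", "CL2", ""), 1), s,
         s + sample(5:30, 1), sample(20:90, 1))
    }))
    kept <- clan_disambiguate(hits)
    expect_equal(clan_disambiguate(kept), kept)
    best <- clan_subset_oracle(hits)
    if (!isTRUE(all.equal(sum(kept$score), best$score)))
      mismatches <- mismatches + 1L
    expect_lte(sum(kept$score), best$score)
  }
  # greedy rarely misses the optimum on small instances
  expect_lte(mismatches, 6L)
})

test_that("refined hits are a subset of de novo hits under perfect transfer", {
  # transfer is exact when query == seed protein, so refined <= denovo
  bm <- small_benchmark()
  db <- bm$db
  da <- db$domain_annotations
  pid <- da$protein_id[1]
  qseq <- db$index$protein_seq[[pid]]
  hit <- smith_waterman(qseq, qseq, query_id = "q", target_id = pid)
  refined <- annotate_domains(qseq, "q", db, hit, mode = "refine")
  denovo <- annotate_domains(qseq, "q", db, hit, mode = "denovo")
  if (nrow(refined))
    expect_true(all(refined$model_id %in% denovo$model_id))
})
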