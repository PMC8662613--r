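## Seed-and-extend local protein search against the reference proteins.
## The aligner is a full Smith-Waterman with affine gaps (C++ core); a
## shared-k-mer prefilter supplies the candidate set, reproducing the
## fast/sensitive/iterative trade-off structure of translated-search tools
## without their SIMD machinery.

.scheme_cache <- new.env(parent = emptyenv())

#' Alignment scoring scheme
#'
#' Bundles a symmetric substitution matrix, affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`), and Karlin-Altschul
#' calibration constants used to turn raw scores into bit scores and
#' E-values. `default_scoring()` returns BLOSUM62 with gap open 11 / extend
#' 1 and the standard gapped constants lambda = 0.267, K = 0.041.
#'
#' E-values use a fixed effective search space (`search_space`, default
#' 1e6 residues) rather than the momentary database size, so that reported
#' E-values — and therefore annotation reports — are invariant under
#' taxon-restricted database subsetting. Rankings are unaffected by this
#' choice.
#'
#' @param matrix square integer substitution matrix with residue rownames.
#' @param gap_open,gap_extend positive gap penalties.
#' @param lambda,K Karlin-Altschul constants.
#' @param search_space effective target search space in residues.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix, gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, search_space = 1e6) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            identical(rownames(matrix), colnames(matrix)),
            isTRUE(all(matrix == t(matrix))),
            gap_open > 0, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 search_space = search_space),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
default_scoring <- function() {
  if (is.null(.scheme_cache$default)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .scheme_cache$default <- scoring_scheme(e$BLOSUM62)
  }
  .scheme_cache$default
}

.encode_protein <- function(seq, scheme) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(chars, rownames(scheme$matrix))
  if (anyNA(code))
    stop("residue outside the scoring alphabet: ",
         paste(unique(chars[is.na(code)]), collapse = ","), call. = FALSE)
  code - 1L
}

.bit_score <- function(raw, scheme)
  (scheme$lambda * raw - log(scheme$K)) / log(2)

.evalue <- function(raw, m, scheme)
  scheme$K * m * scheme$search_space * exp(-scheme$lambda * raw)

#' Optimal local alignment of two proteins
#'
#' Full-matrix Smith-Waterman with affine gaps. Co-optimal alignments are
#' resolved deterministically: smallest query start, then smallest target
#' start. An all-negative comparison yields the empty alignment with raw
#' score 0.
#'
#' @param q,t protein strings.
#' @param scheme a [scoring_scheme()].
#' @param query_id,target_id ids carried into the hit.
#' @return object of class `alignment_hit` with fields `raw_score`,
#'   `bit_score`, `evalue`, 1-based inclusive `query_start/end` and
#'   `target_start/end`, `aligned_pairs` (two-column matrix of matched
#'   columns, strictly increasing in both coordinates) and
#'   `percent_identity`.
#' @export
smith_waterman <- function(q, t, scheme = default_scoring(),
                           query_id = "query", target_id = "target") {
  if (!nzchar(q) || !nzchar(t)) stop("empty sequence", call. = FALSE)
  qi <- .encode_protein(q, scheme)
  ti <- .encode_protein(t, scheme)
  r <- sw_align_cpp(qi, ti, scheme$matrix,
                    as.integer(scheme$gap_open), as.integer(scheme$gap_extend))
  pairs <- cbind(query_pos = r$qpos, target_pos = r$tpos)
  pid <- if (nrow(pairs)) 100 * mean(qi[r$qpos] == ti[r$tpos]) else 0
  structure(list(
    query_id = query_id, target_id = target_id,
    raw_score = r$score,
    bit_score = .bit_score(r$score, scheme),
    evalue = .evalue(r$score, nchar(q), scheme),
    query_start = r$qstart, query_end = r$qend,
    target_start = r$tstart, target_end = r$tend,
    aligned_pairs = pairs, percent_identity = pid,
    frame = NA_character_), class = "alignment_hit")
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("hit %s -> %s: raw=%d bits=%.1f E=%.2e q[%s-%s] t[%s-%s] id=%.1f%%\n",
              x$query_id, x$target_id, x$raw_score, x$bit_score, x$evalue,
              x$query_start, x$query_end, x$target_start, x$target_end,
              x$percent_identity))
  invisible(x)
}

#' Search parameters and sensitivity presets
#'
#' Presets mirror the speed/sensitivity ladder of iterative translated
#' search: `fast` (k = 5, at least 2 shared k-mers), `sensitive` (k = 3, at
#' least 1), and `iterative` which runs fast and re-searches only the
#' unmatched queries with sensitive. Default reporting cutoffs are E-value
#' <= 1e-3 and bit score >= 60.
#'
#' @param preset one of "fast", "sensitive", "iterative".
#' @param kmer_size,min_shared_kmers seed filter controls (overrides).
#' @param evalue_cutoff,min_bit_score reporting cutoffs.
#' @return list of class `search_params`.
#' @export
search_params <- function(preset = c("fast", "sensitive", "iterative"),
                          kmer_size = NULL, min_shared_kmers = NULL,
                          evalue_cutoff = 1e-3, min_bit_score = 60) {
  preset <- match.arg(preset)
  def <- switch(preset,
                fast = list(k = 5L, min = 2L),
                sensitive = list(k = 3L, min = 1L),
                iterative = list(k = 5L, min = 2L))
  k <- if (is.null(kmer_size)) def$k else as.integer(kmer_size)
  if (k < 2L) stop("kmer_size must be >= 2", call. = FALSE)
  structure(list(preset = preset, kmer_size = k,
                 min_shared_kmers = if (is.null(min_shared_kmers)) def$min
                                    else as.integer(min_shared_kmers),
                 evalue_cutoff = evalue_cutoff,
                 min_bit_score = min_bit_score), class = "search_params")
}

.protein_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Build a k-mer index over the reference proteins
#'
#' Every length-k substring of every reference protein is indexed with its
#' (protein, offset) posting.
#'
#' @param db a `ref_db`.
#' @param k word size (>= 2).
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(db, k) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  seqs <- db$proteins$sequence
  ids <- db$proteins$protein_id
  lens <- nchar(seqs)
  keep <- lens >= k
  km <- lapply(which(keep), function(i) .protein_kmers(seqs[i], k))
  dt <- data.table(
    target = rep(ids[keep], times = pmax(lens[keep] - k + 1L, 0L)),
    kmer = unlist(km, use.names = FALSE),
    pos = unlist(lapply(pmax(lens[keep] - k + 1L, 0L), seq_len),
                 use.names = FALSE))
  setkey(dt, kmer)
  structure(list(dt = dt, k = k), class = "kmer_index")
}

#' Look up the postings of a k-mer
#' @param index a `kmer_index`.
#' @param kmers character vector of k-mers.
#' @return data.table of (kmer, target, pos) postings.
#' @export
kmer_lookup <- function(index, kmers) {
  index$dt[data.table(kmer = kmers), on = "kmer", nomatch = 0L]
}

.candidates <- function(index, qseq, min_shared) {
  qk <- unique(.protein_kmers(qseq, index$k))
  if (!length(qk)) return(character(0))
  m <- index$dt[data.table(kmer = qk), on = "kmer", nomatch = 0L]
  if (!nrow(m)) return(character(0))
  cnt <- m[, list(nk = uniqueN(kmer)), by = target]
  sort(cnt[nk >= min_shared]$target)
}

.sort_hits <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  ev <- vapply(hits, `[[`, numeric(1), "evalue")
  bs <- vapply(hits, `[[`, numeric(1), "bit_score")
  tg <- vapply(hits, `[[`, character(1), "target_id")
  hits[order(ev, -bs, tg, method = "radix")]
}

.search_one <- function(qid, qseq, db, params, index, scheme) {
  cand <- .candidates(index, qseq, params$min_shared_kmers)
  if (!length(cand)) return(list())
  seqs <- db$proteins$sequence[match(cand, db$proteins$protein_id)]
  hits <- Map(function(tid, tseq)
    smith_waterman(qseq, tseq, scheme, query_id = qid, target_id = tid),
    cand, seqs)
  keep <- vapply(hits, function(h)
    h$evalue <= params$evalue_cutoff && h$bit_score >= params$min_bit_score,
    logical(1))
  .sort_hits(unname(hits[keep]))
}

#' Search protein queries against the reference database
#'
#' Candidates are targets sharing at least `min_shared_kmers` distinct
#' k-mers with the query; each candidate is aligned by [smith_waterman()];
#' hits passing both cutoffs are kept, sorted by (E-value ascending, bit
#' score descending, target id ascending). The `iterative` preset runs
#' `fast` first and re-searches only the unmatched queries with
#' `sensitive`.
#'
#' @param queries named character vector of protein sequences (or an
#'   `AAStringSet`).
#' @param db a `ref_db`.
#' @param params a [search_params()].
#' @param scheme a [scoring_scheme()].
#' @param index optional prebuilt [build_kmer_index()] matching
#'   `params$kmer_size`.
#' @return list with `hits` (named list: query id -> list of
#'   `alignment_hit`, possibly empty) and `unmatched` (character vector of
#'   query ids with no passing hit).
#' @export
search <- function(queries, db, params = search_params("fast"),
                   scheme = default_scoring(), index = NULL) {
  if (is(queries, "AAStringSet"))
    queries <- setNames(as.character(queries), names(queries))
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique names", call. = FALSE)
  if (params$preset == "iterative") {
    p_fast <- search_params("fast",
                            evalue_cutoff = params$evalue_cutoff,
                            min_bit_score = params$min_bit_score)
    r1 <- search(queries, db, p_fast, scheme, index)
    if (!length(r1$unmatched)) return(r1)
    p_sens <- search_params("sensitive",
                            evalue_cutoff = params$evalue_cutoff,
                            min_bit_score = params$min_bit_score)
    r2 <- search(queries[r1$unmatched], db, p_sens, scheme)
    hits <- r1$hits
    hits[names(r2$hits)] <- r2$hits
    return(list(hits = hits, unmatched = r2$unmatched, params = params))
  }
  if (is.null(index)) index <- build_kmer_index(db, params$kmer_size)
  if (index$k != params$kmer_size)
    stop("index word size does not match params", call. = FALSE)
  hits <- lapply(names(queries), function(qid)
    .search_one(qid, queries[[qid]], db, params, index, scheme))
  names(hits) <- names(queries)
  unmatched <- names(queries)[vapply(hits, length, integer(1)) == 0L]
  list(hits = hits, unmatched = unmatched, params = params)
}

#' Translated (blastx-like) search of nucleotide queries
#'
#' Each query is translated in all six frames; each frame is searched in
#' protein space; hit coordinates are mapped back to forward-strand
#' nucleotide positions and only the best frame per (query, target) pair is
#' kept.
#'
#' @param queries named character vector of nucleotide sequences.
#' @inheritParams search
#' @return as [search()]; each hit carries a `frame` field and
#'   nucleotide-space `query_start`/`query_end`.
#' @export
blastx_search <- function(queries, db, params = search_params("fast"),
                          scheme = default_scoring(), index = NULL) {
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique names", call. = FALSE)
  if (is.null(index)) index <- build_kmer_index(db, params$kmer_size)
  hits <- vector("list", length(queries))
  names(hits) <- names(queries)
  for (qid in names(queries)) {
    nuc <- queries[[qid]]
    if (nchar(nuc) < 3L * params$kmer_size) { hits[[qid]] <- list(); next }
    frames <- six_frame(nuc)
    fhits <- list()
    for (fr in frames) {
      if (nchar(fr$protein) < params$kmer_size) next
      sub <- search(setNames(fr$protein, qid), db, params, scheme, index)
      for (h in sub$hits[[qid]]) {
        a <- fr$map(h$query_start); b <- fr$map(h$query_end)
        h$query_start <- min(a, b); h$query_end <- max(a, b)
        h$frame <- fr$frame
        fhits[[length(fhits) + 1L]] <- h
      }
    }
    if (length(fhits)) {
      # best frame per target
      tg <- vapply(fhits, `[[`, character(1), "target_id")
      fhits <- lapply(split(seq_along(fhits), tg), function(ix)
        .sort_hits(fhits[ix])[[1L]])
      fhits <- .sort_hits(unname(fhits))
    }
    hits[[qid]] <- fhits
  }
  unmatched <- names(queries)[vapply(hits, length, integer(1)) == 0L]
  list(hits = hits, unmatched = unmatched, params = params)
}

#' Best seed ortholog of a query
#'
#' The entry point to orthology resolution: the first hit of the ranked,
#' cutoff-filtered hit list (ties were already broken by E-value, bit score,
#' then target id).
#'
#' @param hits list of `alignment_hit` sorted per the [search()] contract.
#' @return an `alignment_hit`, or `NULL` when no hit passes.
#' @export
best_seed_ortholog <- function(hits) {
  if (!length(hits)) return(NULL)
  hits[[1L]]
}

#' Write hits as conventional 12-column tabular output
#'
#' Columns: query, target, pident, length, mismatches, gapopens, qstart,
#' qend, tstart, tend, evalue, bitscore. Alignment length counts all
#' columns including gaps.
#'
#' @param result a [search()] result.
#' @param path output file.
#' @export
write_hits <- function(result, path) {
  rows <- list()
  for (qid in names(result$hits)) for (h in result$hits[[qid]]) {
    np <- nrow(h$aligned_pairs)
    span <- (h$query_end - h$query_start + 1L) +
            (h$target_end - h$target_start + 1L) - np
    nid <- round(h$percent_identity / 100 * np)
    gaps <- 0L
    if (np > 1L) {
      dq <- diff(h$aligned_pairs[, 1L]); dt_ <- diff(h$aligned_pairs[, 2L])
      gaps <- sum(dq > 1L) + sum(dt_ > 1L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      query = h$query_id, target = h$target_id,
      pident = sprintf("%.1f", h$percent_identity),
      length = span, mismatches = np - nid, gapopens = gaps,
      qstart = h$query_start, qend = h$query_end,
      tstart = h$target_start, tend = h$target_end,
      evalue = sprintf("%.2e", h$evalue),
      bitscore = sprintf("%.1f", h$bit_score), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
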