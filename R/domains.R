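## Protein-domain annotation in three modes: transfer from the seed
## ortholog through the alignment, realignment refinement of transferred
## hits, and full de novo PSSM scanning. Gapless position-specific scoring
## with per-model gathering (GA) thresholds and clan competition preserves
## the semantics of profile-based domain calling with an exactly testable
## scoring core.

.empty_domain_hits <- function()
  data.frame(query_id = character(0), model_id = character(0),
             clan_id = character(0), start = integer(0), end = integer(0),
             score = numeric(0), mode = character(0),
             stringsAsFactors = FALSE)

#' Map a target-coordinate interval onto the query through an alignment
#'
#' Uses the matched columns of an `alignment_hit`. Interval endpoints that
#' fall in gaps snap inward to the nearest aligned column; an interval
#' wholly outside the aligned region maps to nothing.
#'
#' @param hit an `alignment_hit`.
#' @param target_interval `c(start, end)` in target coordinates.
#' @return `c(start, end)` in query coordinates, or `NULL`.
#' @export
map_coordinates <- function(hit, target_interval) {
  p <- hit$aligned_pairs
  if (!nrow(p)) return(NULL)
  s <- target_interval[1L]; e <- target_interval[2L]
  i1 <- which(p[, 2L] >= s)
  i2 <- which(p[, 2L] <= e)
  if (!length(i1) || !length(i2)) return(NULL)
  lo <- i1[1L]; hi <- i2[length(i2)]
  if (lo > hi) return(NULL)
  unname(c(p[lo, 1L], p[hi, 1L]))
}

#' Transfer the seed ortholog's domains onto the query
#'
#' Every domain annotation of the seed protein whose interval maps into the
#' query through the seed alignment becomes a `transferred` hit carrying the
#' source score. Domains outside the aligned region are silently lost — a
#' structural false-negative source that the refinement mode cannot
#' recover.
#'
#' @param db a `ref_db`.
#' @param query_id query id for the reported hits.
#' @param seed_hit the seed `alignment_hit` (query vs seed protein).
#' @return data.frame of domain hits (possibly empty).
#' @export
transfer_domains <- function(db, query_id, seed_hit) {
  da <- db$domain_annotations
  da <- da[da$protein_id == seed_hit$target_id, , drop = FALSE]
  out <- .empty_domain_hits()
  for (i in seq_len(nrow(da))) {
    qi <- map_coordinates(seed_hit, c(da$start[i], da$end[i]))
    if (is.null(qi)) next
    m <- db$domain_models[[da$model_id[i]]]
    out <- rbind(out, data.frame(
      query_id = query_id, model_id = da$model_id[i],
      clan_id = if (is.null(m)) "" else m$clan_id,
      start = qi[1L], end = qi[2L], score = da$score[i],
      mode = "transferred", stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

.encode20 <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA_ALPHABET)
  code[is.na(code)] <- 0L   # unknown residues score -1 per position
  code - 1L
}

#' Best gapless placement of a domain model in a window
#'
#' Maximises the summed per-position PSSM score over all offsets of the
#' model against the window. The model may be truncated only where it
#' overhangs the window edges (prefix/suffix truncation); ties are broken
#' by the smallest window start. Residues outside the 20-letter alphabet
#' score -1 per position.
#'
#' @param seq_window protein subsequence (non-empty).
#' @param model a domain model from `db$domain_models`.
#' @return list with `score`, `start`, `end` (1-based inclusive positions
#'   in the window) and `model_start`, `model_end`.
#' @export
pssm_score <- function(seq_window, model) {
  if (!nzchar(seq_window)) stop("empty window", call. = FALSE)
  r <- pssm_best_cpp(.encode20(seq_window), model$pssm)
  list(score = r$score, start = r$win_start, end = r$win_end,
       model_start = r$model_start, model_end = r$model_end)
}

#' Refine a transferred domain hit by realignment
#'
#' Rescores the window `[start - pad, end + pad]` (clipped to the query)
#' against the model. The hit is kept — with updated coordinates and score
#' and mode `refined` — iff the rescore meets the model's GA threshold;
#' otherwise it is dropped. Refinement can only remove or adjust hits,
#' never add them.
#'
#' @param query_seq query protein string.
#' @param transferred one row of a transferred-hit data.frame.
#' @param db a `ref_db`.
#' @param pad window padding in residues (default 10).
#' @return a one-row data.frame, or `NULL` when the hit is dropped.
#' @export
realign_refine <- function(query_seq, transferred, db, pad = 10L) {
  m <- db$domain_models[[transferred$model_id]]
  if (is.null(m))
    stop("model not present in database: ", transferred$model_id,
         call. = FALSE)
  L <- nchar(query_seq)
  ws <- max(1L, transferred$start - pad)
  we <- min(L, transferred$end + pad)
  sc <- pssm_score(substring(query_seq, ws, we), m)
  if (sc$score < m$ga_threshold) return(NULL)
  data.frame(query_id = transferred$query_id, model_id = m$model_id,
             clan_id = m$clan_id, start = ws + sc$start - 1L,
             end = ws + sc$end - 1L, score = sc$score, mode = "refined",
             stringsAsFactors = FALSE)
}

#' De novo domain scan of a query
#'
#' Scans every model of the database over the full sequence, keeps hits
#' meeting their GA threshold, applies clan competition, and returns hits
#' sorted by start.
#'
#' @param query_seq protein string.
#' @param db a `ref_db`.
#' @param query_id reported query id.
#' @param overlap_frac clan-competition overlap fraction (default 0.5).
#' @return data.frame of `denovo` domain hits.
#' @export
denovo_scan <- function(query_seq, db, query_id = "query",
                        overlap_frac = 0.5) {
  hits <- .empty_domain_hits()
  for (m in db$domain_models) {
    sc <- pssm_score(query_seq, m)
    if (sc$score >= m$ga_threshold)
      hits <- rbind(hits, data.frame(
        query_id = query_id, model_id = m$model_id, clan_id = m$clan_id,
        start = sc$start, end = sc$end, score = sc$score, mode = "denovo",
        stringsAsFactors = FALSE))
  }
  hits <- clan_disambiguate(hits, overlap_frac)
  hits <- hits[order(hits$start, hits$model_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Clan competition between overlapping domain hits
#'
#' Hits are processed by descending score (ties: smaller start, then
#' model_id). A hit is kept unless it overlaps an already-kept hit of the
#' same non-empty clan by more than `overlap_frac` of the shorter of the
#' two intervals. Clan-less hits (empty `clan_id`) never compete. The
#' operation is idempotent.
#'
#' @param hits data.frame of domain hits on one query.
#' @param overlap_frac allowed overlap fraction (default 0.5).
#' @return the surviving hits.
#' @export
clan_disambiguate <- function(hits, overlap_frac = 0.5) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$score, hits$start, hits$model_id)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (nzchar(hits$clan_id[i])) {
      for (j in which(keep)) {
        if (hits$clan_id[j] != hits$clan_id[i] || !nzchar(hits$clan_id[j]))
          next
        ov <- min(hits$end[i], hits$end[j]) -
              max(hits$start[i], hits$start[j]) + 1L
        shorter <- min(hits$end[i] - hits$start[i],
                       hits$end[j] - hits$start[j]) + 1L
        if (ov > overlap_frac * shorter) { ok <- FALSE; break }
      }
    }
    keep[i] <- ok
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Domain annotation driver for one query
#'
#' Applies the selected mode: `transfer` maps the seed's domains through
#' the alignment; `refine` additionally rescores each transferred hit and
#' keeps only those meeting GA; `denovo` ignores the transfer route and
#' scans all models.
#'
#' @param query_seq protein string.
#' @param query_id reported id.
#' @param db a `ref_db`.
#' @param seed_hit the seed `alignment_hit` (required for transfer/refine).
#' @param mode one of `"transfer"`, `"refine"`, `"denovo"`, `"none"`.
#' @param pad,overlap_frac tuning knobs (see [realign_refine()],
#'   [clan_disambiguate()]).
#' @return data.frame of domain hits.
#' @export
annotate_domains <- function(query_seq, query_id, db, seed_hit = NULL,
                             mode = c("transfer", "refine", "denovo",
                                      "none"),
                             pad = 10L, overlap_frac = 0.5) {
  mode <- match.arg(mode)
  if (mode == "none") return(.empty_domain_hits())
  if (mode == "denovo")
    return(denovo_scan(query_seq, db, query_id, overlap_frac))
  if (is.null(seed_hit)) return(.empty_domain_hits())
  tr <- transfer_domains(db, query_id, seed_hit)
  if (mode == "transfer") return(tr)
  out <- .empty_domain_hits()
  for (i in seq_len(nrow(tr))) {
    r <- realign_refine(query_seq, tr[i, ], db, pad)
    if (!is.null(r)) out <- rbind(out, r)
  }
  rownames(out) <- NULL
  out
}
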