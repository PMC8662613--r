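# Independent oracles, written before the implementations they check and
# kept free of package internals.

# full-DP affine-gap local alignment, score only (Gotoh), pure R
sw_oracle <- function(q, t, mat, gap_open = 11, gap_extend = 1) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    srow <- mat[qc[i - 1L], tc]
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_extend,
                     E[i, j - 1L] - gap_extend)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_extend,
                     F[i - 1L, j] - gap_extend)
      h <- max(0, H[i - 1L, j - 1L] + srow[j - 1L], E[i, j], F[i, j])
      H[i, j] <- h
      if (h > best) best <- h
    }
  }
  best
}

# re-derive an alignment's raw score from its matched columns + gap costs
rescore_traceback <- function(hit, q, t, scheme) {
  p <- hit$aligned_pairs
  if (!nrow(p)) return(0)
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  s <- sum(scheme$matrix[cbind(qc[p[, 1]], tc[p[, 2]])])
  if (nrow(p) > 1) {
    gaps <- c(diff(p[, 1]) - 1L, diff(p[, 2]) - 1L)
    for (g in gaps[gaps > 0])
      s <- s - scheme$gap_open - g * scheme$gap_extend
  }
  s
}

# lineage-intersection LCA: last common element of root-first lineages
lca_oracle <- function(tree, taxa) {
  lins <- lapply(taxa, function(t) lineage(tree, t))
  common <- Reduce(intersect, lins)
  common[length(common)]
}

# brute-force parent-walk lineage
lineage_oracle <- function(tree, t) {
  out <- integer(0)
  cur <- as.integer(t)
  repeat {
    out <- c(cur, out)
    p <- unname(tree$parent[[as.character(cur)]])
    if (p == cur) break
    cur <- p
  }
  out
}

# exhaustive (frame, stop) ORF enumeration: for every stop codon in every
# frame, walk upstream codon-by-codon to the previous stop, recording the
# upstream-most start codon
orf_oracle <- function(contig, table = 11L, min_aa = 30L) {
  gcode <- Biostrings::getGeneticCode(as.character(table))
  names(gcode) <- gsub("U", "T", names(gcode))
  stops <- names(gcode)[gcode == "*"]
  starts <- if (as.character(table) == "11") c("ATG", "GTG", "TTG")
            else "ATG"
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  L <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rc(contig)
    for (f in 1:3) {
      nc <- (L - f + 1L) %/% 3L
      if (nc < 1L) next
      cod <- substring(s, f + 3L * (0:(nc - 1L)), f + 3L * (0:(nc - 1L)) + 2L)
      for (si in which(cod %in% stops)) {
        a <- NA_integer_
        k <- si - 1L
        while (k >= 1L && !(cod[k] %in% stops)) {
          if (cod[k] %in% starts) a <- k
          k <- k - 1L
        }
        if (is.na(a) || si - a < min_aa) next
        aa <- unname(gcode[cod[a:(si - 1L)]])
        aa[is.na(aa)] <- "X"
        aa[1L] <- "M"
        p1 <- f + 3L * (a - 1L); p2 <- f + 3L * si - 1L
        if (strand == "+") { st <- p1; en <- p2 }
        else { st <- L - p2 + 1L; en <- L - p1 + 1L }
        out[[length(out) + 1L]] <- data.frame(
          start = st, end = en, strand = strand,
          protein = paste(aa, collapse = ""), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0)))
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force gapless PSSM placement over all offsets
pssm_oracle <- function(window, model) {
  res <- strsplit(window, "", fixed = TRUE)[[1]]
  W <- length(res); L <- model$length
  best <- NULL
  for (d in (1 - L):(W - 1)) {
    i0 <- max(1, 1 - d); i1 <- min(L, W - d)
    if (i1 < i0) next
    s <- 0
    for (i in i0:i1) {
      r <- res[i + d]
      s <- s + unname(if (r %in% colnames(model$pssm)) model$pssm[i, r]
                      else -1)
    }
    if (is.null(best) || s > best$score ||
        (s == best$score && (i0 + d) < best$start))
      best <- list(score = s, start = i0 + d, end = i1 + d)
  }
  best
}

# exhaustive best conflict-free subset for clan competition (<= ~12 hits)
clan_subset_oracle <- function(hits, overlap_frac = 0.5) {
  n <- nrow(hits)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!nzchar(hits$clan_id[i]) || hits$clan_id[i] != hits$clan_id[j]) next
    ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1
    shorter <- min(hits$end[i] - hits$start[i],
                   hits$end[j] - hits$start[j]) + 1
    if (ov > overlap_frac * shorter) conflict[i, j] <- TRUE
  }
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1L && any(conflict[sel, sel])) next
    sc <- sum(hits$score[sel])
    if (is.null(best) || sc > best$score) best <- list(score = sc, sel = sel)
  }
  best
}

# per-pair gene-tree LCA walk: orthologs iff the LCA is a speciation node
gene_lca_type <- function(fam, leaf_a, leaf_b) {
  nd <- fam$nodes
  node_of <- setNames(fam$leaves$node_id, fam$leaves$leaf_id)
  path_to_root <- function(i) {
    out <- integer(0)
    while (i != 0L) { out <- c(out, i); i <- nd$parent[i] }
    out
  }
  pa <- path_to_root(node_of[[leaf_a]])
  pb <- path_to_root(node_of[[leaf_b]])
  lca_node <- intersect(pa, pb)[1L]
  nd$type[lca_node]
}

# term-set precision against a truth set
term_precision <- function(predicted, truth) {
  if (!length(predicted)) return(NA_real_)
  length(intersect(predicted, truth)) / length(predicted)
}
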