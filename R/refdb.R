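## The reference-database bundle: proteins, hierarchical orthologous groups,
## pairwise orthology, per-protein functional annotations, and domain models
## with per-position scoring matrices. Stored on disk as a directory of
## plain-text tables so that simulated databases are diffable and
## versionable.

ANNOTATION_SOURCES <- c("GO", "KEGG_ko", "KEGG_pathway", "KEGG_module",
                        "EC", "BiGG", "CAZy", "name")

.empty_proteins <- function()
  data.frame(protein_id = character(0), tax_id = integer(0),
             sequence = character(0), stringsAsFactors = FALSE)

.empty_ogs <- function() {
  d <- data.frame(og_id = character(0), level = integer(0),
                  description = character(0), cog_categories = character(0),
                  stringsAsFactors = FALSE)
  d$members <- list()
  d
}

.empty_orthologs <- function()
  data.frame(protein_a = character(0), protein_b = character(0),
             stringsAsFactors = FALSE)

.empty_annotations <- function() {
  d <- data.frame(protein_id = character(0), source = character(0),
                  stringsAsFactors = FALSE)
  d$terms <- list()
  d
}

.empty_domain_annotations <- function()
  data.frame(protein_id = character(0), model_id = character(0),
             start = integer(0), end = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# vectorised "do both ends of each pair share at least one OG"
.pairs_share_og <- function(protein_ogs, pairs) {
  if (!nrow(pairs)) return(logical(0))
  id <- seq_len(nrow(pairs))
  oa <- protein_ogs[pairs$protein_a]
  ob <- protein_ogs[pairs$protein_b]
  da <- data.table(id = rep(id, lengths(oa)),
                   og = as.character(unlist(oa, use.names = FALSE)))
  db_ <- data.table(id = rep(id, lengths(ob)),
                    og = as.character(unlist(ob, use.names = FALSE)))
  hit <- unique(merge(da, db_, by = c("id", "og"))$id)
  id %in% hit
}

#' Assemble and validate a reference database
#'
#' The in-memory form of the reference bundle. All referential-integrity
#' and consistency invariants are checked: unique protein ids over leaf
#' species; orthologous groups (OGs) with at least two members, each
#' member's species inside the OG level's subtree, and hierarchical nesting
#' (a protein's OG at a deeper level must be a subset of its OG at any
#' enclosing level); symmetric, OG-supported pairwise orthology; annotation
#' sources from the closed vocabulary; domain-model matrices whose row
#' count equals the model length; domain coordinates inside their protein.
#'
#' @param taxonomy a [taxonomy()] tree.
#' @param proteins data.frame `protein_id`, `tax_id`, `sequence`.
#' @param ogs data.frame `og_id`, `level`, `description`,
#'   `cog_categories`, plus a list-column `members` of protein-id vectors.
#' @param orthologs data.frame `protein_a`, `protein_b` (unordered pairs).
#' @param annotations data.frame `protein_id`, `source`, plus list-column
#'   `terms`.
#' @param domain_models named list; each element a list with `model_id`,
#'   `clan_id` (may be `""`), `length`, `pssm` (length x 20 integer matrix,
#'   columns named by the amino-acid alphabet) and `ga_threshold`.
#' @param domain_annotations data.frame `protein_id`, `model_id`, `start`,
#'   `end`, `score` (1-based inclusive residue coordinates).
#' @param validate run the validator (default TRUE).
#' @return object of class `ref_db`.
#' @export
ref_db <- function(taxonomy, proteins = .empty_proteins(),
                   ogs = .empty_ogs(), orthologs = .empty_orthologs(),
                   annotations = .empty_annotations(),
                   domain_models = list(),
                   domain_annotations = .empty_domain_annotations(),
                   validate = TRUE) {
  stopifnot(inherits(taxonomy, "taxonomy_tree"))
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  orthologs <- as.data.frame(orthologs, stringsAsFactors = FALSE)
  if (nrow(orthologs)) {
    a <- pmin(orthologs$protein_a, orthologs$protein_b)
    b <- pmax(orthologs$protein_a, orthologs$protein_b)
    orthologs <- unique(data.frame(protein_a = a, protein_b = b,
                                   stringsAsFactors = FALSE))
    orthologs <- orthologs[order(orthologs$protein_a, orthologs$protein_b), ,
                           drop = FALSE]
    rownames(orthologs) <- NULL
  }
  db <- structure(list(taxonomy = taxonomy, proteins = proteins, ogs = ogs,
                       orthologs = orthologs, annotations = annotations,
                       domain_models = domain_models,
                       domain_annotations = domain_annotations),
                  class = "ref_db")
  db <- .index_db(db)
  if (validate) validate_database(db)
  db
}

# derived lookup structures, rebuilt deterministically on construction
.index_db <- function(db) {
  idx <- list()
  idx$protein_tax <- setNames(as.integer(db$proteins$tax_id),
                              db$proteins$protein_id)
  idx$protein_seq <- setNames(db$proteins$sequence, db$proteins$protein_id)
  if (nrow(db$ogs)) {
    mem <- db$ogs$members
    flat <- data.frame(og = rep(db$ogs$og_id, lengths(mem)),
                       p = unlist(mem, use.names = FALSE),
                       stringsAsFactors = FALSE)
    idx$protein_ogs <- split(flat$og, flat$p)
    idx$og_members <- setNames(mem, db$ogs$og_id)
  } else {
    idx$protein_ogs <- list()
    idx$og_members <- list()
  }
  idx$pair_keys <- if (nrow(db$orthologs))
    .pair_key(db$orthologs$protein_a, db$orthologs$protein_b) else character(0)
  # O(1) membership test for the pairwise relation
  idx$pair_env <- new.env(parent = emptyenv(), size = length(idx$pair_keys))
  for (k in idx$pair_keys) assign(k, TRUE, envir = idx$pair_env)
  idx$ann_rows <- if (nrow(db$annotations))
    split(seq_len(nrow(db$annotations)), db$annotations$protein_id)
    else list()
  # neighbours in the pairwise relation
  idx$partners <- if (nrow(db$orthologs)) {
    both <- data.frame(p = c(db$orthologs$protein_a, db$orthologs$protein_b),
                       q = c(db$orthologs$protein_b, db$orthologs$protein_a),
                       stringsAsFactors = FALSE)
    split(both$q, both$p)
  } else list()
  db$index <- idx
  db
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf(paste0("ref_db: %d proteins / %d species, %d OGs, %d ortholog",
                     " pairs, %d annotation rows, %d domain models\n"),
              nrow(x$proteins), length(unique(x$proteins$tax_id)),
              nrow(x$ogs), nrow(x$orthologs), nrow(x$annotations),
              length(x$domain_models)))
  invisible(x)
}

.fail_rows <- function(what, rows) {
  stop(what, " (rows ", paste(utils::head(rows, 10L), collapse = ", "),
       if (length(rows) > 10L) ", ..." else "", ")", call. = FALSE)
}

#' Validate a reference database
#'
#' Checks every structural invariant of the bundle and stops with the
#' offending row numbers on the first violation found. Validation is
#' idempotent and is run automatically by [ref_db()] and [load_database()].
#'
#' @param db a `ref_db`.
#' @return `db`, invisibly.
#' @export
validate_database <- function(db) {
  tx <- db$taxonomy
  leaves <- taxonomy_leaves(tx)
  p <- db$proteins
  if (anyDuplicated(p$protein_id))
    .fail_rows("duplicate protein_id", which(duplicated(p$protein_id)))
  if (any(!nzchar(p$sequence)))
    .fail_rows("empty protein sequence", which(!nzchar(p$sequence)))
  if (any(!p$tax_id %in% leaves))
    .fail_rows("protein tax_id is not a leaf species",
               which(!p$tax_id %in% leaves))
  plen <- setNames(nchar(p$sequence), p$protein_id)

  o <- db$ogs
  if (nrow(o)) {
    if (anyDuplicated(o$og_id))
      .fail_rows("duplicate og_id", which(duplicated(o$og_id)))
    if (any(lengths(o$members) < 2L))
      .fail_rows("OG with fewer than 2 members", which(lengths(o$members) < 2L))
    for (i in seq_len(nrow(o))) {
      mem <- o$members[[i]]
      if (!all(mem %in% p$protein_id))
        .fail_rows("OG member not a known protein", i)
      sub <- subtree(tx, o$level[i])
      if (!all(db$index$protein_tax[mem] %in% sub))
        .fail_rows("OG member species outside the level subtree", i)
    }
    # hierarchical nesting: if a protein belongs to OGs G1 (deeper level)
    # and G2 (enclosing level), members(G1) must be a subset of members(G2)
    flat <- data.table(og = rep(o$og_id, lengths(o$members)),
                       p = unlist(o$members, use.names = FALSE))
    pairs <- unique(merge(flat, flat, by = "p",
                          allow.cartesian = TRUE)[, c("og.x", "og.y")])
    pairs <- pairs[pairs$og.x != pairs$og.y, ]
    if (nrow(pairs)) {
      lvl <- setNames(o$level, o$og_id)
      anc <- setNames(lapply(unique(o$level), function(l) lineage(tx, l)),
                      unique(o$level))
      # og.y's level strictly ancestral to og.x's level
      nested <- mapply(function(gx, gy) {
        lx <- lvl[[gx]]; ly <- lvl[[gy]]
        lx != ly && ly %in% anc[[as.character(lx)]]
      }, pairs$og.x, pairs$og.y)
      pairs <- pairs[nested, ]
      for (i in seq_len(nrow(pairs))) {
        g1 <- pairs$og.x[i]; g2 <- pairs$og.y[i]
        if (!all(db$index$og_members[[g1]] %in% db$index$og_members[[g2]]))
          stop("hierarchical OG inconsistency: members of ", g1,
               " not nested in ", g2, call. = FALSE)
      }
    }
  }

  r <- db$orthologs
  if (nrow(r)) {
    if (any(r$protein_a == r$protein_b))
      .fail_rows("self-paired ortholog", which(r$protein_a == r$protein_b))
    known <- r$protein_a %in% p$protein_id & r$protein_b %in% p$protein_id
    if (!all(known)) .fail_rows("ortholog pair references unknown protein",
                                which(!known))
    shared <- .pairs_share_og(db$index$protein_ogs, r)
    if (!all(shared))
      .fail_rows("ortholog pair without a common OG", which(!shared))
  }

  a <- db$annotations
  if (nrow(a)) {
    if (!all(a$source %in% ANNOTATION_SOURCES))
      .fail_rows("annotation source outside the vocabulary",
                 which(!a$source %in% ANNOTATION_SOURCES))
    if (any(lengths(a$terms) == 0L))
      .fail_rows("empty term set", which(lengths(a$terms) == 0L))
    if (!all(a$protein_id %in% p$protein_id))
      .fail_rows("annotation references unknown protein",
                 which(!a$protein_id %in% p$protein_id))
  }

  for (m in db$domain_models) {
    if (nrow(m$pssm) != m$length)
      stop("domain model ", m$model_id, ": pssm row count != length",
           call. = FALSE)
    if (!is.finite(m$ga_threshold))
      stop("domain model ", m$model_id, ": non-finite GA threshold",
           call. = FALSE)
  }

  d <- db$domain_annotations
  if (nrow(d)) {
    if (!all(d$protein_id %in% p$protein_id))
      .fail_rows("domain annotation references unknown protein",
                 which(!d$protein_id %in% p$protein_id))
    if (!all(d$model_id %in% names(db$domain_models)))
      .fail_rows("domain annotation references unknown model",
                 which(!d$model_id %in% names(db$domain_models)))
    bad <- !(d$start >= 1L & d$start <= d$end &
             d$end <= plen[d$protein_id])
    if (any(bad)) .fail_rows("domain coordinates outside protein", which(bad))
  }
  invisible(db)
}

#' Build a database from its component files
#'
#' Thin wrapper over the table readers followed by full validation; the
#' canonical directory layout is handled by [load_database()].
#'
#' @param proteins_faa FASTA of reference proteins; record ids must be
#'   `protein_id tax_id` or plain `protein_id` with tax ids supplied in the
#'   description (` tax=<id>` suffix is also accepted).
#' @param og_tsv,orthologs_tsv,annotations_tsv,domain_models_tsv,domain_pssms_tsv,domain_annotations_tsv
#'   component tables (see [save_database()] for the layouts); `NULL` means
#'   an empty table.
#' @param taxonomy a `taxonomy_tree`.
#' @return a validated `ref_db`.
#' @export
build_database <- function(proteins_faa, og_tsv, orthologs_tsv,
                           annotations_tsv, domain_models_tsv = NULL,
                           domain_pssms_tsv = NULL,
                           domain_annotations_tsv = NULL, taxonomy) {
  ref_db(taxonomy,
         proteins = read_protein_fasta(proteins_faa),
         ogs = if (is.null(og_tsv)) .empty_ogs() else read_og_table(og_tsv),
         orthologs = if (is.null(orthologs_tsv)) .empty_orthologs()
                     else .coerce_cols(.read_tsv(orthologs_tsv,
                                                 c("protein_a", "protein_b")),
                                       .empty_orthologs()),
         annotations = if (is.null(annotations_tsv)) .empty_annotations()
                       else read_annotation_table(annotations_tsv),
         domain_models = if (is.null(domain_models_tsv)) list()
                         else read_domain_models(domain_models_tsv,
                                                 domain_pssms_tsv),
         domain_annotations = if (is.null(domain_annotations_tsv))
           .empty_domain_annotations()
           else .coerce_cols(.read_tsv(domain_annotations_tsv,
                                       c("protein_id", "model_id", "start",
                                         "end", "score")),
                             .empty_domain_annotations()))
}

# force column types to those of a template (read.delim types empty
# columns as logical)
.coerce_cols <- function(tab, template) {
  for (nm in names(template))
    tab[[nm]] <- as(tab[[nm]], class(template[[nm]]))
  tab
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
  if (!all(required %in% names(tab)))
    stop("malformed header in ", basename(path), ": expected columns ",
         paste(required, collapse = ", "), call. = FALSE)
  tab[, required, drop = FALSE]
}

#' @rdname build_database
#' @export
read_protein_fasta <- function(proteins_faa) {
  if (!file.exists(proteins_faa))
    stop("missing table file: ", proteins_faa, call. = FALSE)
  ss <- Biostrings::readAAStringSet(proteins_faa)
  hdr <- names(ss)
  parts <- strsplit(hdr, "[ \t]+")
  pid <- vapply(parts, `[[`, character(1), 1L)
  tax <- vapply(parts, function(x) {
    if (length(x) >= 2L) sub("^tax=", "", x[2L]) else NA_character_
  }, character(1))
  data.frame(protein_id = pid, tax_id = as.integer(tax),
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @rdname build_database
#' @export
read_og_table <- function(og_tsv) {
  tab <- .read_tsv(og_tsv, c("og_id", "level", "description",
                             "cog_categories", "members"))
  out <- tab[, c("og_id", "level", "description", "cog_categories")]
  out$level <- as.integer(out$level)
  out$description <- as.character(out$description)
  out$cog_categories <- as.character(out$cog_categories)
  out$og_id <- as.character(out$og_id)
  out$members <- strsplit(as.character(tab$members), ",", fixed = TRUE)
  out
}

#' @rdname build_database
#' @export
read_annotation_table <- function(annotations_tsv) {
  tab <- .read_tsv(annotations_tsv, c("protein_id", "source", "terms"))
  out <- tab[, c("protein_id", "source")]
  out$protein_id <- as.character(out$protein_id)
  out$source <- as.character(out$source)
  out$terms <- strsplit(as.character(tab$terms), ",", fixed = TRUE)
  out
}

#' @rdname build_database
#' @export
read_domain_models <- function(domain_models_tsv, domain_pssms_tsv) {
  meta <- .read_tsv(domain_models_tsv,
                    c("model_id", "clan_id", "length", "ga_threshold"))
  meta$clan_id[is.na(meta$clan_id)] <- ""
  pss <- .read_tsv(domain_pssms_tsv, c("model_id", "pos", AA_ALPHABET))
  models <- lapply(seq_len(nrow(meta)), function(i) {
    mid <- meta$model_id[i]
    rows <- pss[pss$model_id == mid, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    pssm <- as.matrix(rows[, AA_ALPHABET])
    storage.mode(pssm) <- "integer"
    dimnames(pssm) <- list(NULL, AA_ALPHABET)
    list(model_id = mid, clan_id = as.character(meta$clan_id[i]),
         length = as.integer(meta$length[i]), pssm = pssm,
         ga_threshold = as.numeric(meta$ga_threshold[i]))
  })
  setNames(models, meta$model_id)
}

#' Save / load a reference database directory
#'
#' On-disk layout: `proteins.faa`, `taxonomy.tsv`, `ogs.tsv` (members
#' comma-joined), `orthologs.tsv`, `annotations.tsv` (terms comma-joined),
#' `domain_models.tsv`, `domain_pssms.tsv` (one row per model position),
#' `domain_annotations.tsv`. `load_database(save_database(db, d))`
#' reproduces `db` field for field.
#'
#' @param db a `ref_db`.
#' @param directory database directory.
#' @return `load_database()` returns a validated `ref_db`.
#' @export
save_database <- function(db, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(directory, x)
  ss <- Biostrings::AAStringSet(setNames(db$proteins$sequence,
                                         paste(db$proteins$protein_id,
                                               db$proteins$tax_id)))
  Biostrings::writeXStringSet(ss, f("proteins.faa"))
  save_taxonomy(db$taxonomy, f("taxonomy.tsv"))
  ogs <- db$ogs[, c("og_id", "level", "description", "cog_categories")]
  ogs$members <- vapply(db$ogs$members, paste, character(1), collapse = ",")
  write.table(ogs, f("ogs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(db$orthologs, f("orthologs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ann <- db$annotations[, c("protein_id", "source")]
  ann$terms <- vapply(db$annotations$terms, paste, character(1),
                      collapse = ",")
  write.table(ann, f("annotations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- data.frame(
    model_id = vapply(db$domain_models, `[[`, character(1), "model_id"),
    clan_id = vapply(db$domain_models, `[[`, character(1), "clan_id"),
    length = vapply(db$domain_models, `[[`, integer(1), "length"),
    ga_threshold = vapply(db$domain_models, `[[`, numeric(1), "ga_threshold"),
    stringsAsFactors = FALSE)
  write.table(meta, f("domain_models.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pss <- do.call(rbind, lapply(db$domain_models, function(m) {
    d <- as.data.frame(m$pssm)
    names(d) <- AA_ALPHABET
    cbind(data.frame(model_id = m$model_id, pos = seq_len(nrow(d)),
                     stringsAsFactors = FALSE), d)
  }))
  if (is.null(pss))
    pss <- cbind(data.frame(model_id = character(0), pos = integer(0)),
                 as.data.frame(matrix(integer(0), 0, 20,
                                      dimnames = list(NULL, AA_ALPHABET))))
  write.table(pss, f("domain_pssms.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(db$domain_annotations, f("domain_annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(directory)
}

#' @rdname save_database
#' @export
load_database <- function(directory) {
  f <- function(x) {
    p <- file.path(directory, x)
    if (!file.exists(p)) stop("missing table file: ", x, call. = FALSE)
    p
  }
  taxonomy <- load_taxonomy(f("taxonomy.tsv"))
  build_database(f("proteins.faa"), f("ogs.tsv"), f("orthologs.tsv"),
                 f("annotations.tsv"), f("domain_models.tsv"),
                 f("domain_pssms.tsv"), f("domain_annotations.tsv"),
                 taxonomy = taxonomy)
}

#' Restrict a database to a taxonomic clade
#'
#' Keeps only the proteins of species inside `subtree(t)`; OG memberships
#' are intersected with the kept proteins and OGs dropping below two
#' members are removed (a group needs at least two members by definition);
#' pairwise orthologies are restricted to kept proteins that still share a
#' surviving OG; annotations and domain annotations are restricted; domain
#' models (reference-wide objects) are kept. The result validates.
#'
#' @param db a `ref_db`.
#' @param t tax_id of the clade to keep.
#' @return a `ref_db`; a warning is emitted if no proteins remain.
#' @export
subset_by_taxon <- function(db, t) {
  keep_sp <- intersect(taxonomy_leaves(db$taxonomy), subtree(db$taxonomy, t))
  keep <- db$proteins$tax_id %in% keep_sp
  proteins <- db$proteins[keep, , drop = FALSE]
  rownames(proteins) <- NULL
  if (nrow(proteins) == 0L)
    warning("subset to taxon ", t, " leaves zero proteins", call. = FALSE)
  kept_ids <- proteins$protein_id

  ogs <- db$ogs
  if (nrow(ogs)) {
    ogs$members <- lapply(ogs$members, function(m) m[m %in% kept_ids])
    ogs <- ogs[lengths(ogs$members) >= 2L, , drop = FALSE]
    rownames(ogs) <- NULL
  }
  og_of <- if (nrow(ogs)) {
    flat <- data.frame(og = rep(ogs$og_id, lengths(ogs$members)),
                       p = unlist(ogs$members, use.names = FALSE),
                       stringsAsFactors = FALSE)
    split(flat$og, flat$p)
  } else list()

  orth <- db$orthologs
  if (nrow(orth)) {
    both <- orth$protein_a %in% kept_ids & orth$protein_b %in% kept_ids
    orth <- orth[both, , drop = FALSE]
    if (nrow(orth))
      orth <- orth[.pairs_share_og(og_of, orth), , drop = FALSE]
    rownames(orth) <- NULL
  }

  ann <- db$annotations[db$annotations$protein_id %in% kept_ids, ,
                        drop = FALSE]
  rownames(ann) <- NULL
  dom <- db$domain_annotations[
    db$domain_annotations$protein_id %in% kept_ids, , drop = FALSE]
  rownames(dom) <- NULL

  ref_db(db$taxonomy, proteins, ogs, orth, ann, db$domain_models, dom)
}

#' Field-by-field equality of two databases
#'
#' Order-insensitive comparison of every component table; used by the
#' round-trip tests.
#'
#' @param a,b `ref_db` objects.
#' @return TRUE or a character description of the first difference.
#' @export
db_equal <- function(a, b) {
  norm_df <- function(d, key) {
    d <- d[do.call(order, d[key]), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  if (!identical(norm_df(a$taxonomy$nodes, "tax_id"),
                 norm_df(b$taxonomy$nodes, "tax_id")))
    return("taxonomy differs")
  if (!identical(norm_df(a$proteins, "protein_id"),
                 norm_df(b$proteins, "protein_id")))
    return("proteins differ")
  oa <- a$ogs; ob <- b$ogs
  oa$members <- lapply(oa$members, sort)
  ob$members <- lapply(ob$members, sort)
  if (!isTRUE(all.equal(norm_df(oa, "og_id"), norm_df(ob, "og_id"),
                        check.attributes = FALSE)))
    return("ogs differ")
  if (!identical(norm_df(a$orthologs, c("protein_a", "protein_b")),
                 norm_df(b$orthologs, c("protein_a", "protein_b"))))
    return("orthologs differ")
  na <- a$annotations; nb <- b$annotations
  na$terms <- lapply(na$terms, sort)
  nb$terms <- lapply(nb$terms, sort)
  if (!isTRUE(all.equal(norm_df(na, c("protein_id", "source")),
                        norm_df(nb, c("protein_id", "source")),
                        check.attributes = FALSE)))
    return("annotations differ")
  if (!isTRUE(all.equal(a$domain_models[sort(names(a$domain_models))],
                        b$domain_models[sort(names(b$domain_models))],
                        check.attributes = FALSE)))
    return("domain models differ")
  if (!isTRUE(all.equal(norm_df(a$domain_annotations,
                                c("protein_id", "model_id", "start")),
                        norm_df(b$domain_annotations,
                                c("protein_id", "model_id", "start")),
                        check.attributes = FALSE)))
    return("domain annotations differ")
  TRUE
}
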