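## Functional-term transfer from the ortholog set to the query, and the
## end-to-end annotation driver (search -> scope -> orthologs -> transfer
## -> domains).

TERM_SOURCES <- c("GO", "KEGG_ko", "KEGG_pathway", "KEGG_module", "EC",
                  "BiGG", "CAZy")

.terms_of <- function(db, ids, source) {
  rows <- unlist(db$index$ann_rows[ids], use.names = FALSE)
  if (is.null(rows) || !length(rows)) return(list())
  a <- db$annotations[rows, , drop = FALSE]
  a <- a[a$source == source, , drop = FALSE]
  setNames(a$terms, a$protein_id)
}

#' Transfer functional terms from an ortholog set
#'
#' For each annotation source, the query receives either the union of the
#' orthologs' terms (`policy = "union"`, the default permissive rule) or,
#' under `policy = "majority"`, the terms present in at least
#' `f * n_annotated` of the orthologs, where `n_annotated` counts only
#' orthologs carrying at least one term for that source (so sparse sources
#' are not diluted by unannotated members). The preferred name is the most
#' frequent `name` term among orthologs (ties: lexicographically
#' smallest); the COG category and description are taken from the scope
#' OG. Term sets are deduplicated and lexicographically sorted.
#'
#' @param db a `ref_db`.
#' @param ortholog_set an [orthologs_of()] result.
#' @param policy `"union"` or `"majority"`.
#' @param majority_f fraction for the majority rule (default 0.5).
#' @param seed_hit optional `alignment_hit` supplying `seed_evalue` and
#'   `seed_score` (the bit score).
#' @return object of class `functional_annotation`.
#' @export
transfer_annotations <- function(db, ortholog_set, policy = c("union",
                                                              "majority"),
                                 majority_f = 0.5, seed_hit = NULL) {
  policy <- match.arg(policy)
  seed <- ortholog_set$scope$seed_protein_id
  ids <- ortholog_set$orthologs$protein_id
  terms <- setNames(vector("list", length(TERM_SOURCES)), TERM_SOURCES)
  for (src in TERM_SOURCES) {
    per <- .terms_of(db, ids, src)
    if (!length(per)) { terms[[src]] <- character(0); next }
    if (policy == "union") {
      terms[[src]] <- sort(unique(unlist(per, use.names = FALSE)))
    } else {
      n_ann <- length(per)
      cnt <- table(unlist(lapply(per, unique), use.names = FALSE))
      terms[[src]] <- sort(names(cnt)[cnt >= majority_f * n_ann])
    }
  }
  nm <- .terms_of(db, ids, "name")
  preferred <- ""
  if (length(nm)) {
    cnt <- table(unlist(nm, use.names = FALSE))
    best <- max(cnt)
    preferred <- sort(names(cnt)[cnt == best])[1L]
  }
  scope <- ortholog_set$scope
  og_row <- db$ogs[match(scope$chosen_og, db$ogs$og_id), , drop = FALSE]
  all_ogs <- ogs_of(db, seed)
  og_string <- paste(paste0(all_ogs$og_id, "@",
                            taxon_name(db$taxonomy, all_ogs$level)),
                     collapse = ",")
  structure(list(
    query_id = ortholog_set$query_id,
    seed_ortholog = seed,
    seed_evalue = if (is.null(seed_hit)) NA_real_ else seed_hit$evalue,
    seed_score = if (is.null(seed_hit)) NA_real_ else seed_hit$bit_score,
    og_string = og_string,
    max_annot_level = if (nrow(og_row)) taxon_name(db$taxonomy, og_row$level)
                      else "",
    cog_category = if (nrow(og_row)) og_row$cog_categories else "",
    description = if (nrow(og_row)) og_row$description else "",
    preferred_name = preferred,
    terms = terms,
    pfams = character(0)), class = "functional_annotation")
}

#' @export
print.functional_annotation <- function(x, ...) {
  cat(sprintf("annotation %s: seed=%s og=%s name=%s\n", x$query_id,
              x$seed_ortholog, x$max_annot_level, x$preferred_name))
  for (src in names(x$terms))
    if (length(x$terms[[src]]))
      cat(sprintf("  %s: %s\n", src, paste(x$terms[[src]], collapse = ",")))
  invisible(x)
}

#' Naive best-hit homology transfer (baseline)
#'
#' Transfers every term of the top alignment hit regardless of orthology —
#' the baseline that orthology-restricted transfer is designed to beat when
#' paralogs diverge functionally.
#'
#' @param db a `ref_db`.
#' @param hit the best `alignment_hit` of the query.
#' @return a `functional_annotation` with the hit's own terms.
#' @export
naive_transfer <- function(db, hit) {
  terms <- setNames(vector("list", length(TERM_SOURCES)), TERM_SOURCES)
  for (src in TERM_SOURCES) {
    per <- .terms_of(db, hit$target_id, src)
    terms[[src]] <- sort(unique(unlist(per, use.names = FALSE)))
  }
  nm <- .terms_of(db, hit$target_id, "name")
  structure(list(
    query_id = hit$query_id, seed_ortholog = hit$target_id,
    seed_evalue = hit$evalue, seed_score = hit$bit_score,
    og_string = "", max_annot_level = "", cog_category = "",
    description = "",
    preferred_name = if (length(nm)) sort(unlist(nm))[1L] else "",
    terms = terms, pfams = character(0)), class = "functional_annotation")
}

#' End-to-end annotation of a query set
#'
#' Runs the whole workflow per query: homology search for the seed
#' ortholog, taxonomic-scope selection, expansion to the typed ortholog
#' set, functional-term transfer, and domain annotation. Queries without a
#' passing hit — or, in fixed-scope mode, without an OG at the requested
#' scope — are reported in `unmatched`, never as annotation rows; per-query
#' failures never abort the batch.
#'
#' @param queries named character vector of protein sequences (or
#'   `AAStringSet`).
#' @param db a `ref_db`.
#' @param params a [search_params()].
#' @param scope_mode `"auto"` or a tax_id.
#' @param min_species automatic-scope threshold (default 3).
#' @param target_taxa,allowed_types ortholog-report filters (see
#'   [orthologs_of()]).
#' @param policy,majority_f term-transfer policy (see
#'   [transfer_annotations()]).
#' @param domain_mode `"transfer"` (default), `"refine"`, `"denovo"` or
#'   `"none"`.
#' @param scheme scoring scheme.
#' @param index optional prebuilt k-mer index.
#' @return list with `annotations` (list of `functional_annotation`),
#'   `ortholog_sets`, `domain_hits` (one data.frame), and `unmatched`
#'   (data.frame query/reason).
#' @export
annotate <- function(queries, db, params = search_params("fast"),
                     scope_mode = "auto", min_species = 3L,
                     target_taxa = NULL,
                     allowed_types = c("one2one", "one2many", "many2one",
                                       "many2many"),
                     policy = "union", majority_f = 0.5,
                     domain_mode = "transfer", scheme = default_scoring(),
                     index = NULL) {
  if (is(queries, "AAStringSet"))
    queries <- setNames(as.character(queries), names(queries))
  sr <- search(queries, db, params, scheme, index)
  anns <- list(); osets <- list()
  dh <- .empty_domain_hits()
  unmatched <- data.frame(query = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  for (qid in names(queries)) {
    hit <- best_seed_ortholog(sr$hits[[qid]])
    if (is.null(hit)) {
      unmatched <- rbind(unmatched, data.frame(query = qid,
                                               reason = "no_hit"))
      next
    }
    res <- tryCatch({
      scope <- select_scope(db, hit$target_id, scope_mode, min_species)
      if (is.na(scope$chosen_og)) {
        list(unmapped = TRUE)
      } else {
        oset <- orthologs_of(db, scope, target_taxa, allowed_types,
                             query_id = qid)
        ann <- transfer_annotations(db, oset, policy, majority_f, hit)
        hd <- annotate_domains(queries[[qid]], qid, db, hit, domain_mode)
        ann$pfams <- sort(unique(hd$model_id))
        list(unmapped = FALSE, oset = oset, ann = ann, hd = hd)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      unmatched <- rbind(unmatched, data.frame(query = qid,
                                               reason = conditionMessage(res)))
    } else if (res$unmapped) {
      unmatched <- rbind(unmatched, data.frame(query = qid,
                                               reason = "no_scope"))
    } else {
      anns[[qid]] <- res$ann
      osets[[qid]] <- res$oset
      if (nrow(res$hd)) dh <- rbind(dh, res$hd)
    }
  }
  rownames(dh) <- NULL
  list(annotations = anns, ortholog_sets = osets, domain_hits = dh,
       unmatched = unmatched, search = sr)
}
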