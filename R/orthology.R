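## Orthology resolution: from a seed protein, rank its OG memberships by
## taxonomic specificity, choose the annotation scope, expand to the typed
## ortholog set, and classify pair types from the pairwise relation.
## In-paralog exclusion falls out of the pairwise table: a co-member of the
## scope OG that is not paired with the seed is an in-paralog by
## construction and is never used for transfer.

#' Orthologous groups of a protein, most specific first
#'
#' @param db a `ref_db`.
#' @param protein_id a reference protein id.
#' @return the rows of `db$ogs` containing the protein, ordered by the
#'   taxonomy depth of their level (deepest first), ties broken by og_id.
#' @export
ogs_of <- function(db, protein_id) {
  if (!protein_id %in% db$proteins$protein_id)
    stop("unknown protein: ", protein_id, call. = FALSE)
  gids <- db$index$protein_ogs[[protein_id]]
  if (is.null(gids) || !length(gids))
    return(db$ogs[integer(0), , drop = FALSE])
  rows <- db$ogs[match(gids, db$ogs$og_id), , drop = FALSE]
  d <- taxon_depth(db$taxonomy, rows$level)
  rows <- rows[order(-d, rows$og_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Choose the annotation scope for a seed ortholog
#'
#' In automatic mode the scope is the most specific OG of the seed that
#' spans at least `min_species` distinct species (falling back to the
#' seed's most specific OG when none qualifies) — specific enough to avoid
#' transferring across unwanted lineages, broad enough to avoid
#' singleton/sparse groups. In fixed mode (`mode` a tax_id) the scope is
#' the most specific OG whose level is ancestor-or-equal of the requested
#' taxon; if the seed has no such OG the selection fails explicitly and
#' the query is reported as unmapped at that scope.
#'
#' @param db a `ref_db`.
#' @param seed seed protein id.
#' @param mode `"auto"` or a tax_id (fixed scope).
#' @param min_species minimum distinct species for the automatic rule
#'   (default 3).
#' @return object of class `scope_selection` with fields `seed_protein_id`,
#'   `chosen_og`, `level`, `mode`; `chosen_og` is `NA` when a fixed-mode
#'   selection fails.
#' @export
select_scope <- function(db, seed, mode = "auto", min_species = 3L) {
  ogs <- ogs_of(db, seed)
  sel <- NA_character_; level <- NA_integer_
  if (nrow(ogs)) {
    if (identical(mode, "auto")) {
      nsp <- vapply(ogs$members, function(m)
        length(unique(db$index$protein_tax[m])), integer(1))
      i <- which(nsp >= min_species)[1L]
      if (is.na(i)) i <- 1L          # fallback: most specific OG
      sel <- ogs$og_id[i]; level <- ogs$level[i]
    } else {
      t <- as.integer(mode)
      .check_taxid(db$taxonomy, t)
      lin <- lineage(db$taxonomy, t)
      ok <- ogs$level %in% lin
      i <- which(ok)[1L]
      if (!is.na(i)) { sel <- ogs$og_id[i]; level <- ogs$level[i] }
    }
  }
  structure(list(seed_protein_id = seed, chosen_og = sel, level = level,
                 mode = if (identical(mode, "auto")) "auto"
                        else paste0("fixed(", mode, ")")),
            class = "scope_selection")
}

#' Classify the ortholog type of a pair
#'
#' From the seed's perspective: with `a` the number of co-orthologs in the
#' seed's species paired with `other` (inside the scope OG) and `b` the
#' number in `other`'s species paired with the seed, the type is
#' `(a>1 ? many : one) "2" (b>1 ? many : one)`.
#' `classify_type(seed, other)` is the transpose of
#' `classify_type(other, seed)`.
#'
#' @param db a `ref_db`.
#' @param seed,other protein ids forming a pair of the pairwise relation.
#' @param scope_og og_id of the scope OG containing both.
#' @return one of `"one2one"`, `"one2many"`, `"many2one"`, `"many2many"`.
#' @export
classify_type <- function(db, seed, other, scope_og) {
  has_pair <- function(keys) vapply(keys, exists, logical(1),
                                    envir = db$index$pair_env,
                                    inherits = FALSE, USE.NAMES = FALSE)
  if (!has_pair(.pair_key(seed, other)))
    stop("(", seed, ", ", other, ") is not in the pairwise relation",
         call. = FALSE)
  mem <- db$index$og_members[[scope_og]]
  if (is.null(mem) || !all(c(seed, other) %in% mem))
    stop("both proteins must be members of ", scope_og, call. = FALSE)
  tax <- db$index$protein_tax
  sp_seed <- tax[[seed]]; sp_other <- tax[[other]]
  in_seed_sp <- mem[tax[mem] == sp_seed]
  in_other_sp <- mem[tax[mem] == sp_other]
  a <- sum(in_seed_sp != other & has_pair(.pair_key(in_seed_sp, other)))
  b <- sum(in_other_sp != seed & has_pair(.pair_key(in_other_sp, seed)))
  paste0(if (a > 1L) "many" else "one", "2",
         if (b > 1L) "many" else "one")
}

#' Expand a scope selection to the typed ortholog set
#'
#' Returns every protein of the scope OG that is paired with the seed in
#' the pairwise relation, optionally restricted to species inside the
#' subtree of some target taxon and to a subset of ortholog types, plus the
#' seed itself (typed `"seed"`). Co-members not paired with the seed are
#' its in-paralogs and are excluded.
#'
#' @param db a `ref_db`.
#' @param scope a [select_scope()] result with a valid `chosen_og`.
#' @param target_taxa optional vector of tax_ids; orthologs are kept if
#'   their species lies inside the subtree of any of them.
#' @param allowed_types subset of the four ortholog types (default all).
#' @param query_id id recorded on the set (defaults to the seed).
#' @return object of class `ortholog_set` with a data.frame `orthologs`
#'   (`protein_id`, `species`, `type`; first row is the seed).
#' @export
orthologs_of <- function(db, scope, target_taxa = NULL,
                         allowed_types = c("one2one", "one2many",
                                           "many2one", "many2many"),
                         query_id = scope$seed_protein_id) {
  if (is.na(scope$chosen_og))
    stop("scope selection has no OG (unmapped at this scope)", call. = FALSE)
  seed <- scope$seed_protein_id
  mem <- db$index$og_members[[scope$chosen_og]]
  partners <- db$index$partners[[seed]]
  cand <- intersect(mem, partners)
  tax <- db$index$protein_tax
  if (!is.null(target_taxa)) {
    allowed_sp <- unique(unlist(lapply(target_taxa, function(t)
      subtree(db$taxonomy, t))))
    cand <- cand[tax[cand] %in% allowed_sp]
  }
  types <- vapply(cand, function(p)
    classify_type(db, seed, p, scope$chosen_og), character(1))
  keep <- types %in% allowed_types
  cand <- cand[keep]; types <- types[keep]
  ord <- order(cand)
  orth <- data.frame(
    protein_id = c(seed, cand[ord]),
    species = unname(tax[c(seed, cand[ord])]),
    type = c("seed", unname(types[ord])), stringsAsFactors = FALSE)
  structure(list(query_id = query_id, scope = scope, orthologs = orth),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("ortholog_set for %s: seed=%s og=%s level=%s, %d orthologs\n",
              x$query_id, x$scope$seed_protein_id, x$scope$chosen_og,
              x$scope$level, nrow(x$orthologs) - 1L))
  invisible(x)
}
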