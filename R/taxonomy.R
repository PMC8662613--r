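#' Construct a validated taxonomy tree
#'
#' A taxonomy tree is the coordinate system for every orthologous-group level
#' and every scope decision in the pipeline. It is a rooted tree in which the
#' root is its own parent (NCBI convention), so lineage walks terminate
#' without a sentinel value.
#'
#' @param nodes data.frame with columns `tax_id`, `parent_id`, `name`,
#'   `rank`. `tax_id` must be unique positive integers; exactly one row must
#'   have `parent_id == tax_id` (the root); every other `parent_id` must
#'   resolve to a `tax_id` in the table.
#' @return An object of class `taxonomy_tree`.
#' @export
taxonomy <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("tax_id", "parent_id", "name", "rank")
  if (!all(req %in% names(nodes)))
    stop("taxonomy table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  nodes <- nodes[, req]
  nodes$tax_id <- as.integer(nodes$tax_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$name <- as.character(nodes$name)
  nodes$rank <- as.character(nodes$rank)
  if (anyNA(nodes$tax_id) || any(nodes$tax_id <= 0L))
    stop("tax_id must be positive integers", call. = FALSE)
  if (anyDuplicated(nodes$tax_id)) {
    dup <- nodes$tax_id[duplicated(nodes$tax_id)]
    stop("duplicate tax_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!all(nodes$parent_id %in% nodes$tax_id)) {
    bad <- which(!nodes$parent_id %in% nodes$tax_id)
    stop("parent_id not present in tree (rows ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  root <- nodes$tax_id[nodes$tax_id == nodes$parent_id]
  if (length(root) != 1L)
    stop("tree must have exactly one root (a node that is its own parent); ",
         "found ", length(root), call. = FALSE)

  parent <- setNames(nodes$parent_id, nodes$tax_id)
  kids <- nodes$tax_id[nodes$tax_id != root]
  children <- split(kids, as.character(parent[as.character(kids)]))

  # breadth-first reachability from the root doubles as the cycle check
  depth <- setNames(rep(NA_integer_, nrow(nodes)), nodes$tax_id)
  depth[as.character(root)] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    if (!length(nxt)) break
    depth[as.character(nxt)] <-
      depth[as.character(parent[as.character(nxt)])] + 1L
    frontier <- nxt
  }
  if (anyNA(depth)) {
    orphans <- names(depth)[is.na(depth)]
    stop("nodes unreachable from root (cycle?): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }

  structure(list(nodes = nodes, root = root, parent = parent,
                 children = children, depth = depth),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root=%d (%s), %d leaves\n",
              nrow(x$nodes), x$root,
              x$nodes$name[x$nodes$tax_id == x$root],
              length(taxonomy_leaves(x))))
  invisible(x)
}

#' Read / write the flat taxonomy dump
#'
#' The on-disk format is a UTF-8, tab-separated table with a header row and
#' four columns: `tax_id`, `parent_id`, `name`, `rank`.
#'
#' @param path file path.
#' @return `load_taxonomy()` returns a validated `taxonomy_tree`.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
  taxonomy(tab)
}

#' @rdname load_taxonomy
#' @param tree a `taxonomy_tree`.
#' @export
save_taxonomy <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  write.table(tree$nodes, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

.check_taxid <- function(tree, t) {
  if (!all(as.character(t) %in% names(tree$parent)))
    stop("unknown tax_id: ",
         paste(t[!as.character(t) %in% names(tree$parent)], collapse = ", "),
         call. = FALSE)
}

#' Lineage of a taxon, root first
#'
#' @param tree a `taxonomy_tree`.
#' @param t a tax_id in the tree.
#' @return integer vector of tax_ids, first element the root, last element `t`.
#' @export
lineage <- function(tree, t) {
  .check_taxid(tree, t)
  t <- as.integer(t)
  out <- integer(0)
  cur <- t
  repeat {
    out <- c(cur, out)
    p <- tree$parent[[as.character(cur)]]
    if (p == cur) break
    cur <- p
  }
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is ancestral-or-equal to every input taxon. Works by
#' repeatedly lifting the deeper of two nodes using precomputed depths, so it
#' is O(depth) per pair.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxa non-empty vector of tax_ids.
#' @return a single tax_id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.integer(taxa))
  if (length(taxa) == 0L) stop("lca() needs a non-empty set of taxa",
                               call. = FALSE)
  .check_taxid(tree, taxa)
  Reduce(function(a, b) {
    da <- tree$depth[[as.character(a)]]
    db <- tree$depth[[as.character(b)]]
    while (da > db) { a <- tree$parent[[as.character(a)]]; da <- da - 1L }
    while (db > da) { b <- tree$parent[[as.character(b)]]; db <- db - 1L }
    while (a != b) {
      a <- tree$parent[[as.character(a)]]
      b <- tree$parent[[as.character(b)]]
    }
    a
  }, taxa)
}

#' Ancestry test and subtree extraction
#'
#' `is_ancestor(tree, a, b)` is TRUE iff `a` lies on the lineage of `b`
#' (ancestor-or-equal). `subtree(tree, t)` returns `t` together with all of
#' its descendants.
#'
#' @param tree a `taxonomy_tree`.
#' @param a,b,t tax_ids in the tree.
#' @export
is_ancestor <- function(tree, a, b) {
  .check_taxid(tree, c(a, b))
  a <- as.integer(a); b <- as.integer(b)
  da <- tree$depth[[as.character(a)]]
  cur <- b
  while (tree$depth[[as.character(cur)]] > da)
    cur <- tree$parent[[as.character(cur)]]
  cur == a
}

#' @rdname is_ancestor
#' @return `subtree()`: integer vector of tax_ids (unsorted set).
#' @export
subtree <- function(tree, t) {
  .check_taxid(tree, t)
  out <- integer(0)
  frontier <- as.integer(t)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(tree$children[as.character(frontier)],
                       use.names = FALSE)
  }
  out
}

#' Leaves of a taxonomy tree
#' @param tree a `taxonomy_tree`.
#' @return integer vector of leaf tax_ids.
#' @export
taxonomy_leaves <- function(tree) {
  setdiff(tree$nodes$tax_id,
          unique(tree$parent[names(tree$parent) != as.character(tree$root)]))
}

#' Depth of a taxon (root = 0)
#' @param tree a `taxonomy_tree`.
#' @param t tax_id(s).
#' @return integer depth(s); the specificity order used for OG levels.
#' @export
taxon_depth <- function(tree, t) {
  .check_taxid(tree, t)
  unname(tree$depth[as.character(t)])
}

#' Name of a taxon
#' @param tree a `taxonomy_tree`.
#' @param t tax_id(s).
#' @export
taxon_name <- function(tree, t) {
  .check_taxid(tree, t)
  tree$nodes$name[match(as.integer(t), tree$nodes$tax_id)]
}
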