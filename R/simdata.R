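## Ground-truth generator: random species taxonomy, duplication-loss gene
## families along it, sequence evolution with optional site-rate variation,
## paralog-divergent functional labels, and planted domains. Emits a valid
## reference database plus a held-out query species with an answer key, so
## the whole annotation pipeline can be benchmarked offline against known
## truth.
##
## The substitution model is deliberately the simplest stationary
## replace-with-background draw, and sequences are indel-free: acceptance
## surfaces need controllable divergence and trivially true coordinates,
## not phylogenetic realism.

#' Simulation parameters
#'
#' Defaults describe the standard benchmark world: 16 species, 100 gene
#' families, 200-residue root proteins, duplication rate 0.3 and loss rate
#' 0.1 per unit branch length, substitution rate 1.0 per site per unit
#' branch length, functional divergence probability 0.8 per duplication
#' event, exponential species-tree branch lengths with mean 0.1. Half of
#' the families carry one planted domain of 30 residues evolving at 0.2x
#' the backbone rate (domains are conserved relative to their scaffold).
#'
#' @param n_species,n_families,root_length scale of the simulated world.
#' @param dup_rate,loss_rate birth-death rates per unit branch length.
#' @param subst_rate substitution rate per site per unit branch length.
#' @param func_divergence probability that one child lineage of a
#'   duplication swaps half of its terms for novel ones.
#' @param swap_frac fraction of terms swapped at a divergence event.
#' @param n_base_terms ancestral GO-style terms per family.
#' @param domain_family_frac fraction of families with a planted domain.
#' @param domain_length,domain_rate_scale planted-domain length and
#'   relative substitution rate.
#' @param mean_branch mean of the exponential branch-length draw.
#' @param seed integer; fixes every downstream draw.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_species = 16L, n_families = 100L,
                       root_length = 200L, dup_rate = 0.3, loss_rate = 0.1,
                       subst_rate = 1.0, func_divergence = 0.8,
                       swap_frac = 0.5, n_base_terms = 8L,
                       domain_family_frac = 0.5, domain_length = 30L,
                       domain_rate_scale = 0.2, mean_branch = 0.1,
                       seed = 1L) {
  stopifnot(n_species >= 2L, dup_rate >= 0, loss_rate >= 0, subst_rate >= 0,
            func_divergence >= 0, func_divergence <= 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a species taxonomy
#'
#' Grows a random bifurcating species tree by repeated leaf splitting;
#' internal nodes become the internal taxa used as OG levels. Branch
#' lengths are exponential with mean `mean_branch`.
#'
#' @param n_species number of leaf species (>= 2).
#' @param mean_branch mean branch length (default 0.1).
#' @param seed optional seed; when `NULL` the ambient RNG stream is used.
#' @return list of class `species_sim` with elements `taxonomy` (a
#'   `taxonomy_tree`), `root`, `leaves`, and `brlen` (named per-node branch
#'   length to the parent; `NA` for the root).
#' @export
simulate_taxonomy <- function(n_species, mean_branch = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_species >= 2L)
  parent <- c(1L, 1L, 1L)
  is_leaf <- c(FALSE, TRUE, TRUE)
  next_id <- 4L
  while (sum(is_leaf) < n_species) {
    leaves <- which(is_leaf)
    pick <- leaves[sample.int(length(leaves), 1L)]
    parent[c(next_id, next_id + 1L)] <- pick
    is_leaf[pick] <- FALSE
    is_leaf[c(next_id, next_id + 1L)] <- TRUE
    next_id <- next_id + 2L
  }
  n <- next_id - 1L
  brlen <- c(NA_real_, rexp(n - 1L, 1 / mean_branch))
  nodes <- data.frame(
    tax_id = seq_len(n), parent_id = parent,
    name = ifelse(is_leaf, sprintf("sp%02d", seq_len(n)),
                  sprintf("clade%02d", seq_len(n))),
    rank = ifelse(is_leaf, "species", "clade"), stringsAsFactors = FALSE)
  structure(list(taxonomy = taxonomy(nodes), root = 1L,
                 leaves = which(is_leaf),
                 brlen = setNames(brlen, seq_len(n))),
            class = "species_sim")
}

#' Simulate one gene family by duplication and loss
#'
#' A single gene enters the species-tree root and evolves down every
#' branch; duplication events (rate `dup_rate` per unit branch length)
#' spawn paralog lineages, losses (rate `loss_rate`) prune them. Surviving
#' internal gene-tree nodes are labelled `S` (speciation) or `D`
#' (duplication); unary nodes left by extinction are collapsed with branch
#' lengths summed. Families with fewer than two surviving leaves are
#' rejected and redrawn.
#'
#' @param sp a [simulate_taxonomy()] result.
#' @param dup_rate,loss_rate event rates per unit branch length.
#' @param label_prefix prefix for leaf (protein) ids.
#' @param max_tries rejection limit; exceeding it (a regime where nearly
#'   every family dies) is an error advising new rates.
#' @return list of class `sim_family` with `nodes` (preorder data.frame:
#'   `id`, `parent`, `type` in S/D/leaf, `species`, `brlen`) and `leaves`
#'   (`leaf_id`, `node_id`, `species`).
#' @export
simulate_family <- function(sp, dup_rate = 0.3, loss_rate = 0.1,
                            label_prefix = "", max_tries = 1000L) {
  tx <- sp$taxonomy
  rate <- dup_rate + loss_rate
  descend <- function(node, remain) {
    dt <- if (rate > 0) rexp(1, rate) else Inf
    if (dt < remain) {
      if (runif(1) < loss_rate / rate) return(NULL)
      c1 <- descend(node, remain - dt)
      c2 <- descend(node, remain - dt)
      surv <- Filter(Negate(is.null), list(c1, c2))
      if (length(surv) == 0L) return(NULL)
      if (length(surv) == 1L) {
        s <- surv[[1L]]; s$brlen <- s$brlen + dt; return(s)
      }
      return(list(type = "D", brlen = dt, species = NA_integer_,
                  children = surv))
    }
    kids <- tx$children[[as.character(node)]]
    if (is.null(kids) || !length(kids))
      return(list(type = "leaf", brlen = remain, species = node,
                  children = list()))
    sub <- lapply(kids, function(k)
      descend(k, sp$brlen[[as.character(k)]]))
    surv <- Filter(Negate(is.null), sub)
    if (length(surv) == 0L) return(NULL)
    if (length(surv) == 1L) {
      s <- surv[[1L]]; s$brlen <- s$brlen + remain; return(s)
    }
    list(type = "S", brlen = remain, species = node, children = surv)
  }
  root <- NULL
  count_leaves <- function(nd) {
    if (nd$type == "leaf") return(1L)
    sum(vapply(nd$children, count_leaves, integer(1)))
  }
  for (k in seq_len(max_tries)) {
    cand <- descend(sp$root, 0)
    if (!is.null(cand) && cand$type != "leaf" && count_leaves(cand) >= 2L) {
      root <- cand; break
    }
  }
  if (is.null(root))
    stop("family rejection rate too high; lower loss_rate or raise ",
         "dup_rate", call. = FALSE)

  counters <- new.env(parent = emptyenv())
  acc <- new.env(parent = emptyenv())
  acc$parent <- integer(0); acc$type <- character(0)
  acc$species <- integer(0); acc$brlen <- numeric(0)
  acc$leaf_id <- character(0); acc$leaf_node <- integer(0)
  acc$leaf_sp <- integer(0)
  flatten <- function(nd, parent_id) {
    id <- length(acc$parent) + 1L
    acc$parent[id] <- parent_id; acc$type[id] <- nd$type
    acc$species[id] <- nd$species; acc$brlen[id] <- nd$brlen
    if (nd$type == "leaf") {
      key <- as.character(nd$species)
      counters[[key]] <- (if (is.null(counters[[key]])) 0L
                          else counters[[key]]) + 1L
      k <- length(acc$leaf_id) + 1L
      acc$leaf_id[k] <- sprintf("%st%d_g%d", label_prefix, nd$species,
                                counters[[key]])
      acc$leaf_node[k] <- id; acc$leaf_sp[k] <- nd$species
    }
    for (ch in nd$children) flatten(ch, id)
  }
  flatten(root, 0L)
  structure(list(
    nodes = data.frame(id = seq_along(acc$parent), parent = acc$parent,
                       type = acc$type, species = acc$species,
                       brlen = acc$brlen, stringsAsFactors = FALSE),
    leaves = data.frame(leaf_id = acc$leaf_id, node_id = acc$leaf_node,
                        species = acc$leaf_sp, stringsAsFactors = FALSE)),
    class = "sim_family")
}

#' True pairwise orthologs of a family
#'
#' Constructive route: at every surviving speciation node, all leaf pairs
#' drawn across its child subtrees are orthologs; duplication nodes
#' contribute none. This is equivalent to the speciation-LCA rule (two
#' genes are orthologs iff their gene-tree LCA is a speciation node).
#'
#' @param fam a `sim_family`.
#' @return data.frame `protein_a`, `protein_b` (one row per unordered
#'   pair; may have zero rows).
#' @export
family_orthologs <- function(fam) {
  nd <- fam$nodes
  leaves_under <- vector("list", nrow(nd))
  acc <- list()
  for (i in rev(seq_len(nrow(nd)))) {
    if (nd$type[i] == "leaf") {
      leaves_under[[i]] <-
        fam$leaves$leaf_id[fam$leaves$node_id == i]
      next
    }
    kids <- which(nd$parent == i)
    sets <- leaves_under[kids]
    leaves_under[[i]] <- unlist(sets, use.names = FALSE)
    if (nd$type[i] == "S" && length(sets) >= 2L) {
      for (a in seq_along(sets)) for (b in seq_along(sets)) if (a < b)
        acc[[length(acc) + 1L]] <- expand.grid(
          protein_a = sets[[a]], protein_b = sets[[b]],
          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    }
  }
  if (!length(acc)) return(.empty_orthologs())
  out <- do.call(rbind, acc)
  a <- pmin(out$protein_a, out$protein_b)
  b <- pmax(out$protein_a, out$protein_b)
  out <- unique(data.frame(protein_a = a, protein_b = b,
                           stringsAsFactors = FALSE))
  out[order(out$protein_a, out$protein_b), , drop = FALSE]
}

#' Ortholog type of a true pair, by the counting rule
#'
#' Counts co-orthologs on each side of a pair of the true relation within
#' the species scope of the whole family.
#'
#' @param fam a `sim_family`.
#' @param rel its [family_orthologs()] table.
#' @param a,b leaf ids forming a pair of `rel`.
#' @return one of the four ortholog types, seen from `a`.
#' @export
family_pair_type <- function(fam, rel, a, b) {
  keys <- .pair_key(rel$protein_a, rel$protein_b)
  sp <- setNames(fam$leaves$species, fam$leaves$leaf_id)
  in_a <- fam$leaves$leaf_id[fam$leaves$species == sp[[a]]]
  in_b <- fam$leaves$leaf_id[fam$leaves$species == sp[[b]]]
  na <- sum(in_a != b & .pair_key(in_a, b) %in% keys)
  nb <- sum(in_b != a & .pair_key(in_b, a) %in% keys)
  paste0(if (na > 1L) "many" else "one", "2", if (nb > 1L) "many" else "one")
}

#' Evolve sequences along a gene tree
#'
#' The root sequence is drawn from the background frequencies (uniform
#' over the 20 amino acids unless given). Along a branch of length t, each
#' site substitutes with probability `1 - exp(-r * rate_i * t)` to a
#' residue drawn from the background (possibly the same one). Sequences
#' are indel-free, so coordinates are shared by all leaves.
#'
#' @param fam a `sim_family`.
#' @param root_length residues in the root protein.
#' @param r substitution rate per site per unit branch length.
#' @param seed optional seed (`NULL`: ambient RNG stream).
#' @param root_seq optional root protein string (overrides the draw).
#' @param site_rates optional per-site rate multipliers (length
#'   `root_length`); used to model conserved regions such as domains.
#' @param bg background residue frequencies (length 20).
#' @return list with `sequences` (named character vector per leaf) and
#'   `root` (the root string).
#' @export
evolve_sequences <- function(fam, root_length = 200L, r = 1.0, seed = NULL,
                             root_seq = NULL, site_rates = NULL,
                             bg = rep(1 / 20, 20)) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(r >= 0)
  if (is.null(root_seq)) {
    root_i <- sample.int(20L, root_length, replace = TRUE, prob = bg)
  } else {
    root_i <- match(strsplit(root_seq, "", fixed = TRUE)[[1]], AA_ALPHABET)
    root_length <- length(root_i)
  }
  if (is.null(site_rates)) site_rates <- rep(1, root_length)
  stopifnot(length(site_rates) == root_length)
  nd <- fam$nodes
  seqs <- vector("list", nrow(nd))
  seqs[[1L]] <- root_i
  for (i in seq_len(nrow(nd))[-1L]) {
    par <- seqs[[nd$parent[i]]]
    pr <- 1 - exp(-r * site_rates * nd$brlen[i])
    hit <- runif(root_length) < pr
    s <- par
    if (any(hit))
      s[hit] <- sample.int(20L, sum(hit), replace = TRUE, prob = bg)
    seqs[[i]] <- s
  }
  leaf_chr <- vapply(fam$leaves$node_id, function(ni)
    paste(AA_ALPHABET[seqs[[ni]]], collapse = ""), character(1))
  list(sequences = setNames(leaf_chr, fam$leaves$leaf_id),
       root = paste(AA_ALPHABET[root_i], collapse = ""))
}

.novel_counter <- new.env(parent = emptyenv())

#' Assign functional terms with paralog-specific divergence
#'
#' The root carries `base_terms`. At each duplication node, with
#' probability `p`, one child lineage (chosen uniformly) swaps a fraction
#' `swap_frac` of its terms for fresh novel terms; speciation nodes never
#' change terms. Orthologs therefore share functions while diverged
#' paralog clades do not — the premise that makes orthology-restricted
#' transfer beat naive best-hit transfer.
#'
#' @param fam a `sim_family`.
#' @param base_terms non-empty character vector of ancestral terms.
#' @param p divergence probability per duplication event.
#' @param swap_frac fraction of terms replaced at a divergence event.
#' @param seed optional seed.
#' @return list with `terms` (named list per leaf) and `diverged` (named
#'   logical: did any swap occur on the leaf's root path).
#' @export
assign_functions <- function(fam, base_terms, p = 0.8, swap_frac = 0.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(base_terms) > 0L, p >= 0, p <= 1)
  nd <- fam$nodes
  node_terms <- vector("list", nrow(nd))
  diverged <- logical(nrow(nd))
  node_terms[[1L]] <- base_terms
  # decide victims in node order so the draw sequence is reproducible
  victim <- rep(NA_integer_, nrow(nd))
  for (i in seq_len(nrow(nd))) {
    if (nd$type[i] != "D") next
    if (runif(1) < p) {
      kids <- which(nd$parent == i)
      victim[i] <- kids[sample.int(length(kids), 1L)]
    }
  }
  swap <- function(ts) {
    k <- max(1L, round(swap_frac * length(ts)))
    drop <- sample(ts, k)
    n0 <- if (is.null(.novel_counter$n)) 0L else .novel_counter$n
    novel <- sprintf("GO:9%06d", n0 + seq_len(k))
    .novel_counter$n <- n0 + k
    sort(c(setdiff(ts, drop), novel))
  }
  for (i in seq_len(nrow(nd))[-1L]) {
    par <- nd$parent[i]
    if (!is.na(victim[par]) && victim[par] == i) {
      node_terms[[i]] <- swap(node_terms[[par]])
      diverged[i] <- TRUE
    } else {
      node_terms[[i]] <- node_terms[[par]]
      diverged[i] <- diverged[par]
    }
  }
  # propagate divergence flags down unswapped paths too
  for (i in seq_len(nrow(nd))[-1L])
    diverged[i] <- diverged[i] || diverged[nd$parent[i]]
  list(terms = setNames(node_terms[fam$leaves$node_id],
                        fam$leaves$leaf_id),
       diverged = setNames(diverged[fam$leaves$node_id],
                           fam$leaves$leaf_id))
}

.cog_letters <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1]]

#' Generate a complete benchmark: database, queries and answer key
#'
#' One randomly chosen species is held out: its proteins become the
#' queries (absent from the database); everything else populates the
#' database. OGs are constructed per internal taxon as the family leaves
#' inside that clade (dropped below two members), pairwise orthology is
#' the true speciation-LCA relation restricted to database members,
#' annotations are the simulated term sets plus a per-family name and
#' KEGG ortholog, and planted domains become PSSM models (+5 match / -2
#' mismatch per motif position) with GA thresholds at 0.6 x the motif
#' self-score, so true domains and random sequence separate by
#' construction.
#'
#' @param params a [sim_params()].
#' @return list of class `benchmark`: `db` (a validated `ref_db`),
#'   `queries` (named character vector), `key` (per-query truth:
#'   comma-joined true orthologs and GO terms, planted domain and
#'   coordinates), `heldout` (tax_id), `families` (per-family simulation
#'   objects), `params`.
#' @export
emit_benchmark <- function(params = sim_params()) {
  set.seed(params$seed)
  .novel_counter$n <- 0L
  sp <- simulate_taxonomy(params$n_species, params$mean_branch)
  tx <- sp$taxonomy
  heldout <- sp$leaves[sample.int(length(sp$leaves), 1L)]
  internal <- setdiff(tx$nodes$tax_id, sp$leaves)
  clade_sp <- lapply(internal, function(lv)
    intersect(subtree(tx, lv), sp$leaves))
  n_planted <- round(params$domain_family_frac * params$n_families)

  proteins <- list(); ogs <- list(); pairs <- list(); ann <- list()
  models <- list(); dom_ann <- list(); fams <- list()
  queries <- character(0); key <- list()

  for (i in seq_len(params$n_families)) {
    fam <- simulate_family(sp, params$dup_rate, params$loss_rate,
                           label_prefix = sprintf("f%03d_", i))
    planted <- i <= n_planted
    site_rates <- rep(1, params$root_length)
    dstart <- NA_integer_; dend <- NA_integer_; model_id <- NA_character_
    if (planted) {
      dstart <- sample.int(params$root_length - params$domain_length + 1L, 1L)
      dend <- dstart + params$domain_length - 1L
      site_rates[dstart:dend] <- params$domain_rate_scale
      model_id <- sprintf("PF%04d", i)
    }
    ev <- evolve_sequences(fam, params$root_length, params$subst_rate,
                           site_rates = site_rates)
    base_go <- sprintf("GO:%07d", i * 100L + seq_len(params$n_base_terms))
    fn <- assign_functions(fam, base_go, params$func_divergence,
                           params$swap_frac)
    rel <- family_orthologs(fam)

    leaf_sp <- setNames(fam$leaves$species, fam$leaves$leaf_id)
    db_leaves <- fam$leaves$leaf_id[fam$leaves$species != heldout]
    q_leaves <- setdiff(fam$leaves$leaf_id, db_leaves)

    if (length(db_leaves)) {
      proteins[[i]] <- data.frame(protein_id = db_leaves,
                                  tax_id = unname(leaf_sp[db_leaves]),
                                  sequence = unname(ev$sequences[db_leaves]),
                                  stringsAsFactors = FALSE)
      keep <- rel$protein_a %in% db_leaves & rel$protein_b %in% db_leaves
      if (length(db_leaves) >= 2L && any(keep)) pairs[[i]] <- rel[keep, ]
      mems <- lapply(clade_sp, function(cs)
        db_leaves[leaf_sp[db_leaves] %in% cs])
      keep_lv <- lengths(mems) >= 2L
      if (any(keep_lv)) {
        og <- data.frame(
          og_id = sprintf("OG%04d@%d", i, internal[keep_lv]),
          level = internal[keep_lv],
          description = sprintf("simulated family %d", i),
          cog_categories = .cog_letters[(i - 1L) %% 25L + 1L],
          stringsAsFactors = FALSE)
        og$members <- mems[keep_lv]
        ogs[[length(ogs) + 1L]] <- og
      }
      nl <- length(db_leaves)
      fam_ann <- data.frame(
        protein_id = rep(db_leaves, 3L),
        source = rep(c("GO", "KEGG_ko", "name"), each = nl),
        stringsAsFactors = FALSE)
      fam_ann$terms <- c(unname(fn$terms[db_leaves]),
                         rep(list(sprintf("ko:K%05d", i)), nl),
                         rep(list(sprintf("fam%d", i)), nl))
      ann[[i]] <- fam_ann
    }

    if (planted) {
      motif <- match(strsplit(substring(ev$root, dstart, dend), "",
                              fixed = TRUE)[[1]], AA_ALPHABET)
      pssm <- matrix(-2L, params$domain_length, 20L,
                     dimnames = list(NULL, AA_ALPHABET))
      pssm[cbind(seq_len(params$domain_length), motif)] <- 5L
      ga <- 0.6 * 5 * params$domain_length
      clan <- if (i %% 3L == 0L) "" else sprintf("CL%02d", i %% 7L)
      models[[model_id]] <- list(model_id = model_id, clan_id = clan,
                                 length = params$domain_length, pssm = pssm,
                                 ga_threshold = ga)
      if (length(db_leaves)) {
        sc <- vapply(db_leaves, function(l) {
          res <- match(strsplit(substring(ev$sequences[[l]], dstart, dend),
                                "", fixed = TRUE)[[1]], AA_ALPHABET)
          sum(pssm[cbind(seq_along(res), res)])
        }, numeric(1))
        dom_ann[[length(dom_ann) + 1L]] <- data.frame(
          protein_id = db_leaves, model_id = model_id, start = dstart,
          end = dend, score = unname(sc), stringsAsFactors = FALSE)
      }
    }

    for (q in q_leaves) {
      queries[q] <- ev$sequences[[q]]
      tr <- unique(c(rel$protein_b[rel$protein_a == q],
                     rel$protein_a[rel$protein_b == q]))
      tr <- sort(intersect(tr, db_leaves))
      key[[length(key) + 1L]] <- data.frame(
        query = q, family = i,
        true_orthologs = paste(tr, collapse = ","),
        true_GO = paste(sort(fn$terms[[q]]), collapse = ","),
        domain_model = model_id, domain_start = dstart, domain_end = dend,
        stringsAsFactors = FALSE)
    }
    fams[[i]] <- list(family = fam, sequences = ev, functions = fn,
                      orthologs = rel, planted = planted,
                      model_id = model_id, domain_start = dstart,
                      domain_end = dend)
  }

  db <- ref_db(tx,
               proteins = do.call(rbind, proteins),
               ogs = do.call(rbind, ogs),
               orthologs = if (length(pairs)) do.call(rbind, pairs)
                           else .empty_orthologs(),
               annotations = do.call(rbind, ann),
               domain_models = models,
               domain_annotations = if (length(dom_ann))
                 do.call(rbind, dom_ann) else .empty_domain_annotations())
  structure(list(db = db, queries = queries,
                 key = do.call(rbind, key), heldout = heldout,
                 families = fams, params = params, species = sp),
            class = "benchmark")
}

#' Simulate in-frame sequencing reads from reference proteins
#'
#' Reverse-translates each sampled protein with uniform synonymous codons
#' and cuts one in-frame window of `read_len` nucleotides; half of the
#' reads are reverse-complemented. Each read fully overlaps its source
#' coding sequence in frame, so a translated search should recover the
#' source protein.
#'
#' @param proteins named character vector of protein sequences.
#' @param n number of reads (proteins sampled without replacement if
#'   possible).
#' @param read_len read length in nt (default 150; must be a multiple
#'   of 3).
#' @param seed optional seed.
#' @return list with `reads` (named nucleotide vector) and `truth` (named
#'   source protein ids).
#' @export
sim_reads <- function(proteins, n = length(proteins), read_len = 150L,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(read_len %% 3L == 0L)
  pick <- sample(names(proteins), n, replace = n > length(proteins))
  reads <- character(n); truth <- character(n)
  for (k in seq_len(n)) {
    pid <- pick[k]
    nuc <- reverse_translate(proteins[[pid]])
    L <- nchar(nuc)
    if (L <= read_len) {
      rd <- nuc
    } else {
      st <- 3L * sample.int((L - read_len) %/% 3L + 1L, 1L) - 2L
      rd <- substring(nuc, st, st + read_len - 1L)
    }
    if (k %% 2L == 0L) rd <- revcomp(rd)
    reads[k] <- rd
    truth[k] <- pid
  }
  names(reads) <- sprintf("read%04d", seq_len(n))
  names(truth) <- names(reads)
  list(reads = reads, truth = truth)
}
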