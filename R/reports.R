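## Output writers: the fixed-column annotation TSV, the pairwise-ortholog
## report, and GFF3 parsing / writing / decoration. All writers are
## deterministic; metadata headers are suppressible so that fixed-seed runs
## are byte-reproducible.

ANNOTATION_COLUMNS <- c("query", "seed_ortholog", "evalue", "score",
                        "eggNOG_OGs", "max_annot_lvl", "COG_category",
                        "Description", "Preferred_name", "GOs", "EC",
                        "KEGG_ko", "KEGG_Pathway", "KEGG_Module",
                        "BiGG_Reaction", "CAZy", "PFAMs")

.dash <- function(x) {
  x <- paste(x, collapse = ",")
  if (!nzchar(x)) "-" else x
}

.undash <- function(x) {
  if (identical(x, "-") || !nzchar(x)) character(0)
  else strsplit(x, ",", fixed = TRUE)[[1]]
}

.annotation_row <- function(a) {
  data.frame(
    query = a$query_id, seed_ortholog = a$seed_ortholog,
    evalue = sprintf("%.3e", a$seed_evalue),
    score = sprintf("%.1f", a$seed_score),
    eggNOG_OGs = .dash(a$og_string),
    max_annot_lvl = .dash(a$max_annot_level),
    COG_category = .dash(a$cog_category),
    Description = .dash(a$description),
    Preferred_name = .dash(a$preferred_name),
    GOs = .dash(a$terms$GO), EC = .dash(a$terms$EC),
    KEGG_ko = .dash(a$terms$KEGG_ko),
    KEGG_Pathway = .dash(a$terms$KEGG_pathway),
    KEGG_Module = .dash(a$terms$KEGG_module),
    BiGG_Reaction = .dash(a$terms$BiGG), CAZy = .dash(a$terms$CAZy),
    PFAMs = .dash(a$pfams), stringsAsFactors = FALSE)
}

#' Write the per-query annotation report
#'
#' Tab-separated, fixed documented column order: query, seed_ortholog,
#' evalue, score, eggNOG_OGs, max_annot_lvl, COG_category, Description,
#' Preferred_name, GOs, EC, KEGG_ko, KEGG_Pathway, KEGG_Module,
#' BiGG_Reaction, CAZy, PFAMs. Empty fields are rendered `-`. With
#' `metadata = TRUE`, `#`-prefixed header lines carry the tool version and
#' timestamp; suppress them for byte-reproducible output.
#'
#' @param annotations list of `functional_annotation` objects.
#' @param path output file.
#' @param metadata write `#` metadata header lines (default FALSE).
#' @export
write_annotations <- function(annotations, path, metadata = FALSE) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (metadata) {
    writeLines(c(paste0("## orthomapper v",
                        as.character(utils::packageVersion("orthomapper"))),
                 paste0("## time: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
               con)
  }
  writeLines(paste(c("#query", ANNOTATION_COLUMNS[-1L]), collapse = "\t"),
             con)
  for (a in annotations) {
    r <- .annotation_row(a)
    writeLines(paste(unlist(r[1L, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an annotation report back into annotation objects
#'
#' Inverse of [write_annotations()]: `#` metadata lines are skipped, `-`
#' becomes the empty set.
#'
#' @param path annotation TSV.
#' @return list of `functional_annotation` objects.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr_i <- grep("^#query\t", lines)
  if (!length(hdr_i)) stop("not an annotation report: ", path, call. = FALSE)
  body <- lines[seq_along(lines) > hdr_i[1L] & !startsWith(lines, "#")]
  lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    names(f) <- ANNOTATION_COLUMNS
    und1 <- function(x) { y <- .undash(x); if (length(y)) y[1L] else "" }
    structure(list(
      query_id = f[["query"]], seed_ortholog = f[["seed_ortholog"]],
      seed_evalue = as.numeric(f[["evalue"]]),
      seed_score = as.numeric(f[["score"]]),
      og_string = paste(.undash(f[["eggNOG_OGs"]]), collapse = ","),
      max_annot_level = und1(f[["max_annot_lvl"]]),
      cog_category = und1(f[["COG_category"]]),
      description = und1(f[["Description"]]),
      preferred_name = und1(f[["Preferred_name"]]),
      terms = list(GO = .undash(f[["GOs"]]), EC = .undash(f[["EC"]]),
                   KEGG_ko = .undash(f[["KEGG_ko"]]),
                   KEGG_pathway = .undash(f[["KEGG_Pathway"]]),
                   KEGG_module = .undash(f[["KEGG_Module"]]),
                   BiGG = .undash(f[["BiGG_Reaction"]]),
                   CAZy = .undash(f[["CAZy"]])),
      pfams = .undash(f[["PFAMs"]])), class = "functional_annotation")
  })
}

#' Write the pairwise-ortholog report
#'
#' One row per (query, ortholog): query, seed_ortholog, scope_og,
#' level_name, ortholog_protein, ortholog_species, type. The seed's own
#' row carries type `seed`.
#'
#' @param ortholog_sets list of `ortholog_set` objects.
#' @param db the `ref_db` (for level names).
#' @param path output file.
#' @export
write_orthologs <- function(ortholog_sets, db, path) {
  rows <- lapply(ortholog_sets, function(os) {
    data.frame(query = os$query_id,
               seed_ortholog = os$scope$seed_protein_id,
               scope_og = os$scope$chosen_og,
               level_name = taxon_name(db$taxonomy, os$scope$level),
               ortholog_protein = os$orthologs$protein_id,
               ortholog_species = os$orthologs$species,
               type = os$orthologs$type, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), seed_ortholog = character(0),
               scope_og = character(0), level_name = character(0),
               ortholog_protein = character(0),
               ortholog_species = integer(0), type = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- GFF3 ----

.gff_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

.gff_decode <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%26", "&", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Construct a gff object
#' @param pragmas character vector of leading `##` lines.
#' @param records data.frame with the nine GFF3 columns, attributes held as
#'   a list-column of ordered named character vectors.
#' @param fasta optional character vector: the `##FASTA` section lines.
#' @export
new_gff <- function(pragmas = "##gff-version 3",
                    records = NULL, fasta = character(0)) {
  if (is.null(records)) {
    records <- data.frame(seqid = character(0), source = character(0),
                          type = character(0), start = integer(0),
                          end = integer(0), score = character(0),
                          strand = character(0), phase = character(0),
                          stringsAsFactors = FALSE)
    records$attributes <- list()
  }
  structure(list(pragmas = pragmas, records = records, fasta = fasta),
            class = "gff")
}

#' Parse a GFF3 file
#'
#' Captures all nine columns faithfully, preserves attribute order,
#' percent-decodes attribute values, tolerates and preserves a trailing
#' `##FASTA` section. Malformed feature lines (column count != 9) raise an
#' error naming the line number.
#'
#' @param path GFF3 file.
#' @return object of class `gff`.
#' @export
parse_gff <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  fasta <- character(0)
  fa_i <- which(lines == "##FASTA")
  if (length(fa_i)) {
    fasta <- lines[(fa_i[1L] + 1L):length(lines)]
    lines <- lines[seq_len(fa_i[1L] - 1L)]
  }
  is_comment <- startsWith(lines, "#")
  pragmas <- lines[is_comment]
  feat <- which(!is_comment & nzchar(lines))
  rows <- vector("list", length(feat))
  for (k in seq_along(feat)) {
    i <- feat[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF line ", i, ": expected 9 columns, got ",
           length(f), call. = FALSE)
    attrs <- character(0)
    if (nzchar(f[9L]) && f[9L] != ".") {
      kv <- strsplit(strsplit(f[9L], ";", fixed = TRUE)[[1]], "=",
                     fixed = TRUE)
      attrs <- setNames(vapply(kv, function(p)
        .gff_decode(if (length(p) > 1L) paste(p[-1L], collapse = "=")
                    else ""), character(1)),
        vapply(kv, `[[`, character(1), 1L))
    }
    rows[[k]] <- list(seqid = f[1L], source = f[2L], type = f[3L],
                      start = as.integer(f[4L]), end = as.integer(f[5L]),
                      score = f[6L], strand = f[7L], phase = f[8L],
                      attributes = attrs)
  }
  records <- data.frame(
    seqid = vapply(rows, `[[`, character(1), "seqid"),
    source = vapply(rows, `[[`, character(1), "source"),
    type = vapply(rows, `[[`, character(1), "type"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    score = vapply(rows, `[[`, character(1), "score"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    phase = vapply(rows, `[[`, character(1), "phase"),
    stringsAsFactors = FALSE)
  records$attributes <- lapply(rows, `[[`, "attributes")
  new_gff(pragmas = pragmas, records = records, fasta = fasta)
}

.attr_string <- function(attrs) {
  if (!length(attrs)) return(".")
  paste(paste0(names(attrs), "=", .gff_encode(unname(attrs))),
        collapse = ";")
}

#' Write a gff object
#' @param gff a `gff` object.
#' @param path output file.
#' @export
write_gff <- function(gff, path) {
  stopifnot(inherits(gff, "gff"))   # force the promise before truncating
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(gff$pragmas, con)
  r <- gff$records
  for (i in seq_len(nrow(r))) {
    writeLines(paste(r$seqid[i], r$source[i], r$type[i], r$start[i],
                     r$end[i], r$score[i], r$strand[i], r$phase[i],
                     .attr_string(r$attributes[[i]]), sep = "\t"), con)
  }
  if (length(gff$fasta)) writeLines(c("##FASTA", gff$fasta), con)
  invisible(path)
}

#' Decorate a GFF file with functional annotations
#'
#' Records whose `id_attribute` value matches an annotated query gain the
#' attributes `em_target`, `em_score`, `em_evalue`, `em_OGs`, `em_COG_cat`,
#' `em_desc`, `em_Preferred_name`, `em_GOs`, `em_KEGG_ko` and `em_PFAMs`
#' (empty values omitted). All other records, all coordinates and all
#' existing attributes pass through unchanged; a single `#` comment line
#' records the decoration. Annotation queries matching no record are
#' counted in a warning.
#'
#' @param gff_in input GFF3 path (or a `gff` object).
#' @param annotations list of `functional_annotation`.
#' @param path output path.
#' @param id_attribute attribute key matched against query ids (default
#'   `"ID"`).
#' @return the output path, invisibly.
#' @export
decorate_gff <- function(gff_in, annotations, path, id_attribute = "ID") {
  gff <- if (inherits(gff_in, "gff")) gff_in else parse_gff(gff_in)
  by_q <- setNames(annotations,
                   vapply(annotations, `[[`, character(1), "query_id"))
  used <- character(0)
  r <- gff$records
  for (i in seq_len(nrow(r))) {
    attrs <- r$attributes[[i]]
    id <- if (id_attribute %in% names(attrs)) attrs[[id_attribute]]
          else NA_character_
    if (is.na(id) || !id %in% names(by_q)) next
    a <- by_q[[id]]
    used <- c(used, id)
    em <- c(em_target = a$seed_ortholog,
            em_score = sprintf("%.1f", a$seed_score),
            em_evalue = sprintf("%.3e", a$seed_evalue),
            em_OGs = a$og_string,
            em_COG_cat = a$cog_category,
            em_desc = a$description,
            em_Preferred_name = a$preferred_name,
            em_GOs = paste(a$terms$GO, collapse = ","),
            em_KEGG_ko = paste(a$terms$KEGG_ko, collapse = ","),
            em_PFAMs = paste(a$pfams, collapse = ","))
    em <- em[nzchar(em)]
    r$attributes[[i]] <- c(attrs, em)
  }
  unused <- setdiff(names(by_q), used)
  if (length(unused))
    warning(length(unused), " annotation quer",
            if (length(unused) == 1L) "y" else "ies",
            " matched no GFF record", call. = FALSE)
  gff$records <- r
  gff$pragmas <- c(gff$pragmas, "# functional attributes added by orthomapper")
  write_gff(gff, path)
  invisible(path)
}

#' Strip decoration attributes from a gff object
#'
#' Inverse of [decorate_gff()] for round-trip checks: removes every
#' `em_*` attribute and the decoration comment line.
#'
#' @param gff a `gff` object.
#' @export
strip_decoration <- function(gff) {
  gff$records$attributes <- lapply(gff$records$attributes, function(a)
    a[!startsWith(names(a), "em_")])
  gff$pragmas <- gff$pragmas[gff$pragmas !=
                               "# functional attributes added by orthomapper"]
  gff
}
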