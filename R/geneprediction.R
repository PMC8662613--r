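## Built-in prokaryotic ORF prediction and six-frame translation.
## A deterministic longest-ORF-per-stop finder stands in for a trained gene
## model: the downstream annotation stages, not gene calling, are the point.

.code_cache <- new.env(parent = emptyenv())

# codon -> amino-acid lookup for a translation table, with start-codon set.
# Codons containing N are never starts/stops and translate to X.
.genetic_code <- function(table = 11L) {
  key <- as.character(table)
  if (!is.null(.code_cache[[key]])) return(.code_cache[[key]])
  code <- tryCatch(Biostrings::getGeneticCode(key),
                   error = function(e) stop("unknown translation table: ",
                                            table, call. = FALSE))
  starts <- if (key == "11") c("ATG", "GTG", "TTG") else {
    alt <- attr(code, "alt_init_codons")
    unique(c("ATG", if (!is.null(alt)) gsub("U", "T", alt)))
  }
  obj <- list(code = setNames(as.character(code), gsub("U", "T", names(code))),
              starts = starts,
              stops = gsub("U", "T", names(code))[as.character(code) == "*"])
  .code_cache[[key]] <- obj
  obj
}

.check_nuc <- function(nuc) {
  if (grepl("[^ACGTN]", nuc))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
}

.codons_of <- function(nuc) {
  n <- nchar(nuc) %/% 3L
  if (n == 0L) return(character(0))
  substring(nuc, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

.translate_codons <- function(codons, gc) {
  aa <- unname(gc$code[codons])
  aa[is.na(aa)] <- "X"   # any codon containing N
  aa
}

#' Translate a nucleotide sequence
#'
#' Translates in frame +1 using the chosen translation table. Stop codons
#' are rendered as `*`; codons containing `N` translate to `X`. Start codons
#' are NOT normalised here (a GTG translates to V); normalisation to M is an
#' ORF-level rule applied by [find_orfs()].
#'
#' @param nuc nucleotide string over `{A,C,G,T,N}`, length >= 3. A trailing
#'   partial codon is ignored.
#' @param table NCBI translation-table code (default 11, bacterial).
#' @return amino-acid string.
#' @export
translate <- function(nuc, table = 11L) {
  nuc <- toupper(nuc)
  .check_nuc(nuc)
  if (nchar(nuc) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  gc <- .genetic_code(table)
  paste(.translate_codons(.codons_of(nuc), gc), collapse = "")
}

#' Reverse-complement a nucleotide string
#' @param nuc nucleotide string over `{A,C,G,T,N}`.
#' @export
revcomp <- function(nuc) {
  chartr("ACGTN", "TGCAN",
         vapply(nuc, function(s)
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

#' Six-frame translation with coordinate mapping
#'
#' Returns the six translated frames (+1, +2, +3, -1, -2, -3) of a
#' nucleotide sequence, each with a mapping function from residue index back
#' to 1-based inclusive nucleotide positions on the forward strand.
#'
#' @param nuc nucleotide string.
#' @param table translation-table code.
#' @return list of six entries with elements `frame` (e.g. "+2"), `strand`,
#'   `protein`, and `map(i)` returning `c(nt_start, nt_end)` of residue `i`.
#' @export
six_frame <- function(nuc, table = 11L) {
  nuc <- toupper(nuc)
  .check_nuc(nuc)
  L <- nchar(nuc)
  gc <- .genetic_code(table)
  rc <- revcomp(nuc)
  out <- vector("list", 6)
  idx <- 1L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nuc else rc
    for (f in 1:3) {
      sub <- substring(s, f, L)
      prot <- paste(.translate_codons(.codons_of(sub), gc), collapse = "")
      map <- if (strand == "+") {
        local({ fo <- f; function(i) c(fo + 3L * (i - 1L), fo + 3L * i - 1L) })
      } else {
        # residue i uses positions f+3(i-1) .. f+3i-1 on the reverse strand;
        # reverse-strand position p corresponds to forward position L-p+1
        local({ fo <- f; Lo <- L
          function(i) c(Lo - (fo + 3L * i - 1L) + 1L,
                        Lo - (fo + 3L * (i - 1L)) + 1L) })
      }
      out[[idx]] <- list(frame = paste0(if (strand == "+") "+" else "-", f),
                         strand = strand, protein = prot, map = map)
      idx <- idx + 1L
    }
  }
  out
}

#' Find open reading frames on both strands
#'
#' For every stop codon in each of the six frames, reports at most one ORF:
#' from the upstream-most in-frame start codon (since the previous stop) to
#' that stop. Start codons for table 11 are ATG, GTG, TTG; the start codon
#' is normalised to M in the reported protein. ORFs without a terminating
#' stop (running off the contig) are not reported, and coordinates are
#' always given on the forward strand, 1-based inclusive, including the stop
#' codon.
#'
#' @param contig nucleotide string over `{A,C,G,T,N}`.
#' @param table translation-table code (default 11).
#' @param min_aa minimum protein length in residues (default 30,
#'   approximately the conventional 90 nt cutoff).
#' @param contig_id id used in the output.
#' @return data.frame with columns `contig_id`, `start`, `end`, `strand`,
#'   `protein`, `translation_table`, ordered by (contig, start, strand).
#' @export
find_orfs <- function(contig, table = 11L, min_aa = 30L, contig_id = "contig") {
  contig <- toupper(contig)
  .check_nuc(contig)
  stopifnot(min_aa >= 1L)
  gc <- .genetic_code(table)
  L <- nchar(contig)
  rc <- revcomp(contig)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rc
    for (f in 1:3) {
      codons <- .codons_of(substring(s, f, L))
      if (!length(codons)) next
      is_stop <- codons %in% gc$stops
      is_start <- codons %in% gc$starts
      stops <- which(is_stop)
      prev <- 0L
      for (st in stops) {
        seg <- if (st > prev + 1L) (prev + 1L):(st - 1L) else integer(0)
        cand <- seg[is_start[seg]]
        prev <- st
        if (!length(cand)) next
        a <- cand[1L]
        prot_len <- st - a          # residues excluding the stop
        if (prot_len < min_aa) next
        aa <- .translate_codons(codons[a:(st - 1L)], gc)
        aa[1L] <- "M"
        # positions on the strand-local sequence
        p1 <- f + 3L * (a - 1L)
        p2 <- f + 3L * st - 1L      # includes the stop codon
        if (strand == "+") {
          start <- p1; end <- p2
        } else {
          start <- L - p2 + 1L; end <- L - p1 + 1L
        }
        res[[length(res) + 1L]] <- data.frame(
          contig_id = contig_id, start = start, end = end, strand = strand,
          protein = paste(aa, collapse = ""),
          translation_table = as.integer(table),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protein = character(0), translation_table = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$contig_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict proteins from a set of contigs
#'
#' Runs [find_orfs()] over every contig and names the predicted proteins
#' `contigID_N` in output order.
#'
#' @param contigs named character vector of contig sequences (or an
#'   `DNAStringSet`).
#' @inheritParams find_orfs
#' @return list with `proteins` (named character vector) and `orfs` (the
#'   combined ORF table with a `protein_id` column).
#' @export
predict_genes <- function(contigs, table = 11L, min_aa = 30L) {
  if (methods::is(contigs, "DNAStringSet"))
    contigs <- setNames(as.character(contigs), names(contigs))
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must have unique names", call. = FALSE)
  tabs <- lapply(names(contigs), function(id)
    find_orfs(contigs[[id]], table = table, min_aa = min_aa, contig_id = id))
  orfs <- do.call(rbind, tabs)
  if (is.null(orfs) || nrow(orfs) == 0L)
    return(list(proteins = character(0),
                orfs = cbind(find_orfs("TTTTTT", min_aa = 1000L),
                             protein_id = character(0))))
  n_per <- ave(seq_len(nrow(orfs)), orfs$contig_id, FUN = seq_along)
  orfs$protein_id <- paste0(orfs$contig_id, "_", n_per)
  list(proteins = setNames(orfs$protein, orfs$protein_id), orfs = orfs)
}

#' Emit predicted genes as GFF3 records
#'
#' @param orfs the `orfs` table from [predict_genes()].
#' @return a `gff` object (see [parse_gff()]) with one CDS record per ORF,
#'   attributes `ID` and `partial=00`.
#' @export
orfs_to_gff <- function(orfs) {
  recs <- data.frame(
    seqid = orfs$contig_id, source = "orthomapper", type = "CDS",
    start = orfs$start, end = orfs$end, score = ".", strand = orfs$strand,
    phase = "0", stringsAsFactors = FALSE)
  recs$attributes <- lapply(orfs$protein_id, function(id)
    c(ID = id, partial = "00"))
  new_gff(pragmas = "##gff-version 3", records = recs)
}

#' Reverse-translate a protein using uniformly chosen synonymous codons
#'
#' Used by the simulator to produce coding nucleotide sequences whose frame
#' +1 translation is the input protein. Draws are taken from the current RNG
#' stream.
#'
#' @param protein amino-acid string (no `*`).
#' @param table translation-table code.
#' @return nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, table = 11L) {
  gc <- .genetic_code(table)
  by_aa <- split(names(gc$code), unname(gc$code))
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (!all(aas %in% names(by_aa)))
    stop("protein contains residues not encodable by table ", table,
         call. = FALSE)
  paste(vapply(aas, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}
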