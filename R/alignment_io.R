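# MSA input/output, clade assignment, numbering maps, jackknife replicates
# and site tables.

#' The twenty standard amino acids, alphabetically ordered
#'
#' One-letter codes in lexicographic order. This ordering is used for
#' deterministic tie-breaking of modal residues throughout the package.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.MSA_ALPHABET <- c(AA20, "-", "X")

#' Construct a two-clade multiple sequence alignment
#'
#' A `clade_msa` holds an aligned set of protein sequences partitioned into
#' exactly two named clades (e.g. the two paralog groups GAS6 and PROS1).
#' Gaps are `-`; `X` marks an unknown/ambiguous residue and is treated as
#' missing data everywhere downstream.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned sequences (equal lengths, alphabet
#'   restricted to the 20 amino acids plus `-` and `X`).
#' @param clades named character vector mapping every id to one of exactly
#'   two clade labels.
#' @param clade_levels optional length-2 character giving the clade order.
#'   The first clade plays the "divergent in Type Ia" role (GAS6 in the
#'   motivating family), the second the "divergent in Type Ib" role (PROS1).
#'   Defaults to the order of first appearance.
#' @return An object of class `clade_msa`.
#' @export
clade_msa <- function(ids, seqs, clades, clade_levels = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nc <- unique(nchar(seqs))
  if (length(nc) != 1L)
    stop("alignment error: sequences have differing lengths (",
         paste(nc, collapse = ", "), ")")
  if (nc < 1L) stop("alignment error: zero-length alignment")
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X-]"), seqs)
  if (any(bad))
    stop("alphabet error: illegal character in sequence(s) ",
         paste(ids[bad], collapse = ", "))
  clades <- clades[ids]
  if (any(is.na(clades)))
    stop("clade error: missing clade assignment for ",
         paste(ids[is.na(clades)], collapse = ", "))
  labs <- unique(unname(clades))
  if (length(labs) != 2L)
    stop("clade error: expected exactly 2 clade labels, got ", length(labs))
  if (is.null(clade_levels)) clade_levels <- labs
  if (!setequal(clade_levels, labs) || length(clade_levels) != 2L)
    stop("clade error: clade_levels must name the two clades present")
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs,
                 clades = stats::setNames(as.character(clades), ids),
                 clade_levels = as.character(clade_levels),
                 n_columns = as.integer(nc)),
            class = "clade_msa")
}

#' @export
print.clade_msa <- function(x, ...) {
  tab <- table(factor(x$clades, levels = x$clade_levels))
  cat("clade_msa: ", length(x$ids), " sequences, ", x$n_columns,
      " columns\n", sep = "")
  cat("  clades: ", paste(sprintf("%s (n=%d)", names(tab), tab),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.clade_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Sequence ids belonging to one clade
#' @param msa a [clade_msa()].
#' @param clade clade label.
#' @return character vector of ids.
#' @export
clade_ids <- function(msa, clade) {
  if (!clade %in% msa$clade_levels)
    stop("clade error: unknown clade ", clade)
  msa$ids[msa$clades == clade]
}

#' Read a two-clade alignment from FASTA plus a clade table
#'
#' @param msa_file path to an aligned protein FASTA.
#' @param clades_file path to a TSV with header `id<TAB>clade`; every FASTA
#'   id must be present and exactly two clade labels must occur.
#' @param clade_levels optional clade ordering, see [clade_msa()].
#' @return A validated [clade_msa()]; input sequence order is preserved.
#' @export
read_clade_msa <- function(msa_file, clades_file, clade_levels = NULL) {
  if (!file.exists(msa_file)) stop("no such file: ", msa_file)
  if (!file.exists(clades_file)) stop("no such file: ", clades_file)
  aa <- Biostrings::readAAStringSet(msa_file)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  cl <- utils::read.delim(clades_file, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("id", "clade") %in% names(cl)))
    stop("clade error: clades file must have columns 'id' and 'clade'")
  missing <- setdiff(ids, cl$id)
  if (length(missing))
    stop("clade error: no clade assignment for ",
         paste(missing, collapse = ", "))
  clades <- stats::setNames(cl$clade, cl$id)[ids]
  clade_msa(ids, seqs, clades, clade_levels = clade_levels)
}

#' Write a two-clade alignment to FASTA plus a clade table
#'
#' Inverse of [read_clade_msa()]; writing then reading reproduces the
#' alignment exactly.
#' @param msa a [clade_msa()].
#' @param msa_file,clades_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_clade_msa <- function(msa, msa_file, clades_file) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(msa$seqs), msa_file)
  utils::write.table(data.frame(id = msa$ids,
                                clade = unname(msa$clades[msa$ids])),
                     clades_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(msa_file, clades_file))
}

#' Map alignment columns to ungapped residue positions for one sequence
#'
#' Positions follow the HGVS convention: the initiator methionine (the first
#' residue of the ungapped sequence) is residue 1. Gap columns map to `NA`.
#'
#' @param msa a [clade_msa()].
#' @param id sequence identifier.
#' @return A `numbering_map`: data frame with columns `column` (1-based
#'   alignment column) and `residue` (1-based ungapped position or `NA`),
#'   with the sequence id as attribute `seq_id`.
#' @export
build_numbering_map <- function(msa, id) {
  if (!id %in% msa$ids) stop("unknown sequence id: ", id)
  chars <- strsplit(unname(msa$seqs[id]), "", fixed = TRUE)[[1]]
  nongap <- chars != "-"
  residue <- rep(NA_integer_, length(chars))
  residue[nongap] <- seq_len(sum(nongap))
  structure(data.frame(column = seq_along(chars), residue = residue),
            seq_id = id, class = c("numbering_map", "data.frame"))
}

#' Translate residue positions between isoform numbering systems
#'
#' Isoform numbering differences are piecewise-constant offsets: a table of
#' inclusive ranges `(start, end, offset)` in source coordinates maps source
#' position `p` to `p + offset`. Positions outside every range are unmapped
#' (`NA`), e.g. residues absent from the shorter isoform.
#'
#' @param positions integer vector of source-isoform positions.
#' @param offsets data frame with columns `start`, `end`, `offset`
#'   (non-overlapping inclusive ranges).
#' @return Integer vector of target-isoform positions (`NA` where unmapped).
#' @examples
#' # GAS6 isoform 1 -> isoform 2 (isoform 2 lacks residues 275..321)
#' offs <- data.frame(start = c(1, 322), end = c(274, 721),
#'                    offset = c(0, -43))
#' apply_isoform_offsets(c(37, 322, 300), offs)  # 37, 279, NA
#' @export
apply_isoform_offsets <- function(positions, offsets) {
  stopifnot(all(c("start", "end", "offset") %in% names(offsets)))
  if (any(offsets$end < offsets$start))
    stop("invalid offset range (end < start)")
  o <- offsets[order(offsets$start), , drop = FALSE]
  if (nrow(o) > 1L && any(o$start[-1L] <= o$end[-nrow(o)]))
    stop("overlapping offset ranges")
  out <- rep(NA_integer_, length(positions))
  for (i in seq_len(nrow(o))) {
    in_range <- !is.na(positions) & positions >= o$start[i] &
      positions <= o$end[i]
    out[in_range] <- as.integer(positions[in_range] + o$offset[i])
  }
  out
}

#' Leave-one-out jackknife alignments
#'
#' Generates one alignment per sequence, each with that sequence removed.
#' Columns keep the master alignment's indexing (they are never re-compacted,
#' even if a column becomes all-gap), so that per-column detections from
#' different replicates can be unioned directly.
#'
#' @param msa a [clade_msa()] with at least 3 sequences (each clade must
#'   remain non-empty after removal).
#' @return A list of `length(msa$ids)` `clade_msa` objects, named by the
#'   removed sequence id.
#' @export
jackknife_alignments <- function(msa) {
  n <- length(msa$ids)
  if (n < 3L)
    stop("insufficient data: jackknife needs at least 3 sequences")
  counts <- table(msa$clades)
  if (any(counts < 2L))
    stop("insufficient data: each clade needs >= 2 sequences for jackknife")
  out <- lapply(msa$ids, function(drop) {
    keep <- setdiff(msa$ids, drop)
    clade_msa(keep, msa$seqs[keep], msa$clades[keep],
              clade_levels = msa$clade_levels)
  })
  names(out) <- msa$ids
  out
}

.SITE_METHODS <- c("FD", "B_Ia", "B_Ib", "B_II", "PS", "Ia", "Ib", "II")

.validate_site_table <- function(df) {
  need <- c("aln_col", "gas6_pos1", "gas6_pos2", "gas6_aa",
            "pros1_pos", "pros1_aa", "methods")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("gas6_aa", "pros1_aa")) {
    v <- df[[col]]
    bad <- !is.na(v) & !(v %in% AA20)
    if (any(bad))
      stop("parse error: invalid residue in ", col, ": ",
           paste(unique(v[bad]), collapse = ", "))
  }
  tags <- strsplit(df$methods, ",", fixed = TRUE)
  if (any(lengths(tags) == 0L) || any(is.na(df$methods)) ||
      any(!nzchar(df$methods)))
    stop("parse error: empty method tag set")
  bad <- setdiff(unique(trimws(unlist(tags))), .SITE_METHODS)
  if (length(bad))
    stop("parse error: malformed method tag(s): ",
         paste(bad, collapse = ", "))
  ac <- df$aln_col[!is.na(df$aln_col)]
  if (anyDuplicated(ac))
    stop("parse error: duplicate alignment column(s): ",
         paste(unique(ac[duplicated(ac)]), collapse = ", "))
  g1 <- df$gas6_pos1[!is.na(df$gas6_pos1)]
  if (anyDuplicated(g1))
    stop("parse error: duplicate gas6_pos1 position(s): ",
         paste(unique(g1[duplicated(g1)]), collapse = ", "))
  class(df) <- c("site_table", "data.frame")
  df
}

#' Read a functional-divergence site table
#'
#' Columns: `aln_col` (master alignment column, may be empty), `gas6_pos1`
#' and `gas6_pos2` (position in the first paralog under its two isoform
#' numberings), `gas6_aa`, `pros1_pos`, `pros1_aa`, and `methods` — a
#' comma-separated subset of `FD`, `B_Ia`, `B_Ib`, `B_II`, `PS` (external
#' method tags) and `Ia`, `Ib`, `II` (this package's detector).
#'
#' @param path TSV path with the header above. Lines starting `#` ignored.
#' @return A `site_table` data frame (possibly with zero rows); duplicate
#'   positions are rejected.
#' @export
parse_site_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(aln_col = "integer",
                                         gas6_pos1 = "integer",
                                         gas6_pos2 = "integer",
                                         gas6_aa = "character",
                                         pros1_pos = "integer",
                                         pros1_aa = "character",
                                         methods = "character"))
  .validate_site_table(df)
}

#' Write a site table
#' @param sites a `site_table` data frame (see [parse_site_table()]).
#' @param path output TSV path.
#' @param header_lines optional character vector written as leading `#`
#'   comment lines (provenance: tool version, seed, parameters).
#' @return Invisibly, `path`.
#' @export
write_site_table <- function(sites, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(as.data.frame(sites), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Bundled table of GAS6/PROS1 functionally divergent sites
#'
#' The 78 sites reported to be under functional divergence between the
#' vertebrate paralogs GAS6 and PROS1, with GAS6 positions under both
#' isoform numberings and the external method tags (`FD`, `B_Ia`, `B_Ib`,
#' `B_II`, `PS`).
#' @return A `site_table` with 78 rows.
#' @export
gas6_pros1_sites <- function() {
  parse_site_table(system.file("extdata", "gas6_pros1_divergent_sites.tsv",
                               package = "paralogdiv", mustWork = TRUE))
}
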