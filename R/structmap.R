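# Structural mapping: PDB ingestion, interface / ligand-proximal residue
# detection at a heavy-atom distance cutoff, N-glycosylation sequon
# scanning, and joining divergent sites onto chain residues.

.WATER <- c("HOH", "WAT", "DOD")

#' Read a protein structure from PDB
#'
#' Keeps heavy atoms only (hydrogens and deuteriums dropped), removes
#' waters, and resolves alternate locations by keeping the highest
#' occupancy copy of each atom. HETATM groups (e.g. the glycan unit NAG)
#' are kept as named ligands.
#'
#' @param path PDB file path.
#' @return A `struct_model`: list with `atoms` (data frame: `type`,
#'   `elety`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`,
#'   `elesy`) and `ligands` (character vector of HETATM residue names).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$elesy[is.na(at$elesy)] <- ""
  at$o[is.na(at$o)] <- 1
  elesy <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1L, 1L))
  hyd <- ifelse(nzchar(elesy), elesy, guess) %in% c("H", "D")
  at <- at[!hyd & !(at$resid %in% .WATER), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms in ", path)
  # altloc: keep the highest-occupancy copy of each (chain, resno, insert,
  # elety) atom; ties keep the first record
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  atoms <- data.frame(type = at$type, elety = trimws(at$elety),
                      resid = trimws(at$resid), chain = at$chain,
                      resno = at$resno, insert = at$insert,
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      elesy = trimws(at$elesy), stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms,
                 ligands = unique(atoms$resid[atoms$type == "HETATM"])),
            class = "struct_model")
}

#' @export
print.struct_model <- function(x, ...) {
  ch <- table(x$atoms$chain[x$atoms$type == "ATOM"])
  cat("struct_model: ", nrow(x$atoms), " heavy atoms; chains ",
      paste(sprintf("%s (%d atoms)", names(ch), ch), collapse = ", "),
      "\n", sep = "")
  if (length(x$ligands))
    cat("  ligands: ", paste(x$ligands, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# min distance from each residue in `a` (grouped atoms) to any atom in `b`
.min_res_dist <- function(a, b) {
  bx <- as.matrix(b[, c("x", "y", "z")])
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  ukey <- unique(key)
  out <- vapply(ukey, function(k) {
    ax <- as.matrix(a[key == k, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  first <- a[match(ukey, key), c("chain", "resno", "insert", "resid")]
  first$min_dist <- unname(out)
  rownames(first) <- NULL
  first
}

.contact_set <- function(df, partner, cutoff) {
  df$partner <- partner
  df <- df[df$min_dist < cutoff,
           c("chain", "resno", "insert", "resid", "partner", "min_dist"),
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, cutoff = cutoff, class = c("contact_set", "data.frame"))
}

#' Interface residues between two chains
#'
#' Residues of chain `chain_x` whose minimum heavy-atom distance to any
#' atom of chain `chain_y` is strictly below the cutoff (default 6
#' angstrom, the "less than 6 A" interface criterion).
#'
#' @param struct a [read_structure()] model.
#' @param chain_x,chain_y chain identifiers (protein ATOM records).
#' @param cutoff distance cutoff in angstrom; strict `<`.
#' @return A `contact_set` data frame: `chain`, `resno`, `insert`,
#'   `resid`, `partner`, `min_dist`; attribute `cutoff`.
#' @export
interface_residues <- function(struct, chain_x, chain_y, cutoff = 6.0) {
  at <- struct$atoms[struct$atoms$type == "ATOM", , drop = FALSE]
  a <- at[at$chain == chain_x, , drop = FALSE]
  b <- at[at$chain == chain_y, , drop = FALSE]
  if (!nrow(a)) stop("missing chain: ", chain_x)
  if (!nrow(b)) stop("missing chain: ", chain_y)
  .contact_set(.min_res_dist(a, b), paste0("chain:", chain_y), cutoff)
}

#' Residues proximal to a named ligand
#'
#' Protein residues whose minimum heavy-atom distance to any heavy atom of
#' the ligand (HETATM residue name, e.g. `"NAG"`) is strictly below the
#' cutoff.
#'
#' @inheritParams interface_residues
#' @param ligand HETATM residue name.
#' @return A `contact_set` (see [interface_residues()]).
#' @export
ligand_proximal_residues <- function(struct, ligand = "NAG",
                                     cutoff = 6.0) {
  a <- struct$atoms[struct$atoms$type == "ATOM", , drop = FALSE]
  b <- struct$atoms[struct$atoms$type == "HETATM" &
                    struct$atoms$resid == ligand, , drop = FALSE]
  if (!nrow(b)) stop("ligand absent: ", ligand)
  if (!nrow(a)) stop("no protein atoms")
  .contact_set(.min_res_dist(a, b), paste0("ligand:", ligand), cutoff)
}

#' Scan a protein sequence for N-glycosylation sequons
#'
#' Finds every match of the N-linked glycosylation consensus
#' Asn-X-Ser/Thr (N-X-S/T): position `i` is a sequon when residue `i` is N
#' and residue `i+2` is S or T. The stricter variant excluding proline at
#' X is available behind `exclude_proline` (off by default — the plain
#' consensus).
#'
#' @param sequence amino-acid string (no gaps) or character vector of
#'   residues.
#' @param numbering optional integer vector of per-residue positions
#'   (HGVS: initiator Met = 1); defaults to `1..n`.
#' @param exclude_proline if `TRUE`, skip sequons with P at the X position.
#' @return data frame of hits: `position` (of the Asn), `triplet`.
#' @export
scan_sequons <- function(sequence, numbering = NULL,
                         exclude_proline = FALSE) {
  s <- if (length(sequence) == 1L)
    strsplit(toupper(sequence), "", fixed = TRUE)[[1]] else toupper(sequence)
  n <- length(s)
  if (is.null(numbering)) numbering <- seq_len(n)
  stopifnot(length(numbering) == n)
  hits <- integer(0)
  if (n >= 3L) {
    i <- seq_len(n - 2L)
    ok <- s[i] == "N" & s[i + 2L] %in% c("S", "T")
    if (exclude_proline) ok <- ok & s[i + 1L] != "P"
    hits <- i[ok]
  }
  data.frame(position = numbering[hits],
             triplet = vapply(hits, function(k)
               paste(s[k:(k + 2L)], collapse = ""), character(1)),
    stringsAsFactors = FALSE)
}

# one-letter sequence of a chain's observed residues, in file order
.chain_sequence <- function(struct, chain) {
  at <- struct$atoms[struct$atoms$type == "ATOM" &
                     struct$atoms$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("missing chain: ", chain)
  key <- paste(at$resno, at$insert, sep = "|")
  keep <- !duplicated(key)
  res <- at[keep, c("resno", "insert", "resid"), drop = FALSE]
  aa <- bio3d::aa321(res$resid)
  aa[is.na(aa) | !aa %in% AA20] <- "X"
  list(residues = res, seq = paste(aa, collapse = ""))
}

# map chain residue order -> reference sequence positions via pairwise
# alignment (handles loops missing from the structure)
.align_chain_to_seq <- function(chain_seq, ref_seq, min_identity = 0.8) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chain_seq), Biostrings::AAString(ref_seq),
    type = "global-local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- Biostrings::start(Biostrings::subject(pa))
  chain_pos <- 0L
  map <- rep(NA_integer_, nchar(chain_seq))
  n_match <- 0L; n_aln <- 0L
  for (k in seq_along(p)) {
    pc <- p[k]; sc <- s[k]
    if (pc != "-") chain_pos <- chain_pos + 1L
    if (pc != "-" && sc != "-") {
      map[chain_pos] <- ref_pos
      n_aln <- n_aln + 1L
      if (pc == sc) n_match <- n_match + 1L
    }
    if (sc != "-") ref_pos <- ref_pos + 1L
  }
  if (n_aln == 0L || n_match / n_aln < min_identity)
    stop("ambiguous mapping: chain/sequence alignment identity ",
         signif(if (n_aln) n_match / n_aln else 0, 3),
         " below ", min_identity,
         " over ", n_aln, " aligned residues")
  map
}

#' Map divergent sites onto structure residues
#'
#' Joins a site table to the residues of one chain: each site's alignment
#' column is converted to an ungapped position of the reference sequence
#' (via its numbering map), and the chain's observed residue sequence is
#' aligned to that reference sequence to absorb gaps from unmodelled
#' loops. Sites falling outside the modelled region are reported as
#' unmapped. Optionally flags sites that belong to supplied contact sets.
#'
#' @param sites a `site_table` with `aln_col` filled in.
#' @param msa the [clade_msa()] the sites were detected on.
#' @param seq_id id of the sequence the structure models (must be in the
#'   msa).
#' @param struct a [read_structure()] model.
#' @param chain chain identifier within `struct`.
#' @param contacts optional named list of `contact_set`s; each contributes
#'   a logical column `in_<name>`.
#' @param min_identity minimum chain/sequence alignment identity before
#'   the mapping is declared ambiguous (default 0.8).
#' @return The site table with added columns `chain`, `resno`, `insert`,
#'   `mapped` and one flag column per contact set.
#' @export
map_sites_to_structure <- function(sites, msa, seq_id, struct, chain,
                                   contacts = list(),
                                   min_identity = 0.8) {
  if (any(is.na(sites$aln_col)))
    stop("sites must carry alignment columns")
  nmap <- build_numbering_map(msa, seq_id)
  cs <- .chain_sequence(struct, chain)
  ref_seq <- gsub("-", "", unname(msa$seqs[seq_id]), fixed = TRUE)
  chain_to_ref <- .align_chain_to_seq(cs$seq, ref_seq, min_identity)
  ref_to_chain <- rep(NA_integer_, nchar(ref_seq))
  ref_to_chain[chain_to_ref[!is.na(chain_to_ref)]] <-
    which(!is.na(chain_to_ref))
  out <- as.data.frame(sites, stringsAsFactors = FALSE)
  respos <- nmap$residue[match(out$aln_col, nmap$column)]
  ci <- ifelse(is.na(respos), NA_integer_, ref_to_chain[respos])
  out$chain <- ifelse(is.na(ci), NA_character_, chain)
  out$resno <- cs$residues$resno[ci]
  out$insert <- cs$residues$insert[ci]
  out$mapped <- !is.na(ci)
  for (nm in names(contacts)) {
    cset <- contacts[[nm]]
    key <- paste(cset$chain, cset$resno, cset$insert, sep = "|")
    skey <- paste(out$chain, out$resno, out$insert, sep = "|")
    out[[paste0("in_", nm)]] <- out$mapped & skey %in% key
  }
  out
}
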