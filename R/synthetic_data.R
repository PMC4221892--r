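# Seeded generators for every input the pipeline consumes: null and
# planted-site two-clade alignments, surrogate ddG matrices and toy
# structures. All generators are pure functions of (spec, seed).

#' Simulation specification for two-clade alignments
#'
#' The null model is a single-class (no-divergence) 20-state exchangeable
#' substitution process — uniform exchangeabilities and uniform stationary
#' frequencies — with continuous gamma rate variation across columns
#' (mean 1), run over a symmetric two-clade tree: a root with two stem
#' branches, each leading to a clade whose tips hang on equal-length
#' branches. Defaults reproduce the sampling depth of a vertebrate paralog
#' family: 15 taxa per clade, between-clade identity around 40%, and a
#' within-clade identity of about 50% — on a star topology every pair of
#' clade members attains the clade's maximum divergence, so the tip depth
#' is matched to the most divergent within-clade pairs.
#'
#' @param taxa_per_clade tips per clade (default 15).
#' @param n_columns alignment columns.
#' @param stem_depth stem branch length, substitutions/site (default 0.2).
#' @param clade_depth within-clade tip branch length (default 0.5).
#' @param gamma_shape gamma shape for across-column rate variation
#'   (default 1.0; rates drawn with mean 1).
#' @param eps within-clade substitution error rate for planted sites, in
#'   \[0, 0.5) (default 0.05).
#' @param plan named counts of sites to plant, e.g.
#'   `c(Ia = 10, Ib = 10, II = 10)` (default: none).
#' @param seed integer seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(taxa_per_clade = 15, n_columns = 1000,
                     stem_depth = 0.2, clade_depth = 0.5,
                     gamma_shape = 1.0, eps = 0.05,
                     plan = c(Ia = 0, Ib = 0, II = 0), seed = 1) {
  plan_full <- c(Ia = 0, Ib = 0, II = 0)
  plan_full[names(plan)] <- plan
  if (any(plan_full < 0)) stop("planted-site counts must be >= 0")
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)")
  if (taxa_per_clade < 2) stop("need at least 2 taxa per clade")
  if (n_columns < 1) stop("need at least 1 column")
  if (sum(plan_full) > n_columns)
    stop("planted-site plan exceeds the number of columns")
  if (gamma_shape <= 0 || stem_depth < 0 || clade_depth < 0)
    stop("invalid simulation parameters")
  structure(list(taxa_per_clade = as.integer(taxa_per_clade),
                 n_columns = as.integer(n_columns),
                 stem_depth = stem_depth, clade_depth = clade_depth,
                 gamma_shape = gamma_shape, eps = eps,
                 plan = plan_full, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Symmetric two-clade tree
#'
#' Root with two stem branches of `stem_depth`; each clade node carries
#' `taxa_per_clade` tip branches of `clade_depth`. Tip labels are
#' `<label>_<i>`.
#'
#' @inheritParams sim_spec
#' @param labels length-2 clade labels (default `c("cladeA", "cladeB")`).
#' @return An `ape` `phylo`.
#' @export
two_clade_tree <- function(taxa_per_clade = 15, stem_depth = 0.2,
                           clade_depth = 0.5,
                           labels = c("cladeA", "cladeB")) {
  mk <- function(lab) paste0(
    "(", paste(sprintf("%s_%d:%g", lab, seq_len(taxa_per_clade),
                       clade_depth), collapse = ","),
    "):", stem_depth)
  ape::read.tree(text = paste0("(", mk(labels[1]), ",", mk(labels[2]),
                               ");"))
}

# Evolve columns along a tree under the 20-state Poisson model.
# rates: per-column rate multipliers. Returns tips x columns char matrix.
# P(child == parent | branch d) = 1/20 + 19/20 * exp(-20 d / 19); a change
# lands uniformly on the 19 other states.
.simulate_columns <- function(tree, rates) {
  ncols <- length(rates)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nrow = nnode, ncol = ncols)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, ncols, replace = TRUE)
  eo <- stats::reorder(tree, "postorder")
  edges <- eo$edge[rev(seq_len(nrow(eo$edge))), , drop = FALSE]  # preorder
  lens <- eo$edge.length[rev(seq_len(nrow(eo$edge)))]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; chi <- edges[k, 2L]
    d <- lens[k] * rates
    p_stay <- 1 / 20 + (19 / 20) * exp(-20 * d / 19)
    stay <- stats::runif(ncols) < p_stay
    s <- states[par, ]
    if (any(!stay)) {
      shift <- sample.int(19L, sum(!stay), replace = TRUE)
      s[!stay] <- ((s[!stay] - 1L + shift) %% 20L) + 1L
    }
    states[chi, ] <- s
  }
  m <- matrix(AA20[states[seq_len(ntip), , drop = FALSE]],
              nrow = ntip, ncol = ncols)
  rownames(m) <- tree$tip.label
  m
}

#' Simulate a null two-clade alignment
#'
#' Columns are i.i.d. given their gamma-distributed rate; there is no
#' clade-specific process, so any apparent Type I/II signal is sampling
#' noise — this is the null distribution the detection thresholds are
#' calibrated on.
#'
#' @param spec a [sim_spec()].
#' @param labels clade labels (default `c("cladeA", "cladeB")`).
#' @return A [clade_msa()] with attributes `tree` (the generating
#'   `phylo`) and `rates` (per-column rate multipliers).
#' @export
simulate_null_alignment <- function(spec,
                                    labels = c("cladeA", "cladeB")) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  tree <- two_clade_tree(spec$taxa_per_clade, spec$stem_depth,
                         spec$clade_depth, labels)
  rates <- stats::rgamma(spec$n_columns, shape = spec$gamma_shape,
                         rate = spec$gamma_shape)
  m <- .simulate_columns(tree, rates)
  ids <- rownames(m)
  clades <- stats::setNames(sub("_[0-9]+$", "", ids), ids)
  msa <- clade_msa(ids, apply(m, 1L, paste, collapse = ""), clades,
                   clade_levels = labels)
  attr(msa, "tree") <- tree
  attr(msa, "rates") <- rates
  msa
}

# fix one clade's rows of a column to residue `res`, flipping each
# sequence independently to a random other residue with probability eps
.fixed_column <- function(n, res, eps) {
  out <- rep(res, n)
  flip <- stats::runif(n) < eps
  if (any(flip)) {
    base <- match(res, AA20)
    shift <- sample.int(19L, sum(flip), replace = TRUE)
    out[flip] <- AA20[((base - 1L + shift) %% 20L) + 1L]
  }
  out
}

#' Plant Type Ia / Ib / II divergent sites into an alignment
#'
#' Overwrites randomly chosen disjoint columns with ground-truth divergent
#' patterns. Type II: the first clade is fixed to residue `a`, the second
#' to `b != a`, each sequence independently flipped to a random other
#' residue with probability `eps`. Type Ia: the second clade (PROS1 role)
#' is fixed (error `eps`) while the first clade's residues are drawn
#' uniformly at random; Type Ib is the mirror image.
#'
#' @param msa a [clade_msa()] (typically from
#'   [simulate_null_alignment()]).
#' @param plan named counts `c(Ia=, Ib=, II=)`.
#' @param eps within-clade error rate in \[0, 0.5).
#' @param seed integer seed.
#' @return list: `msa` (modified alignment) and `truth` — data frame
#'   `column`, `type`, `res_a` (first-clade fixed residue, `NA` for Ia),
#'   `res_b` (second-clade fixed residue, `NA` for Ib).
#' @export
plant_divergent_sites <- function(msa, plan, eps = 0.05, seed = 1) {
  plan_full <- c(Ia = 0, Ib = 0, II = 0)
  plan_full[names(plan)] <- plan
  total <- sum(plan_full)
  if (total > msa$n_columns) stop("plan exceeds the number of columns")
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)")
  set.seed(seed)
  mat <- as.matrix(msa)
  ids1 <- clade_ids(msa, msa$clade_levels[1])
  ids2 <- clade_ids(msa, msa$clade_levels[2])
  cols <- sample.int(msa$n_columns, total)
  types <- rep(c("Ia", "Ib", "II"), times = plan_full[c("Ia", "Ib", "II")])
  truth <- data.frame(column = cols, type = types,
                      res_a = NA_character_, res_b = NA_character_,
                      stringsAsFactors = FALSE)
  for (k in seq_len(total)) {
    col <- cols[k]
    if (types[k] == "II") {
      ab <- sample(AA20, 2L)
      mat[ids1, col] <- .fixed_column(length(ids1), ab[1], eps)
      mat[ids2, col] <- .fixed_column(length(ids2), ab[2], eps)
      truth$res_a[k] <- ab[1]; truth$res_b[k] <- ab[2]
    } else if (types[k] == "Ia") {
      b <- sample(AA20, 1L)
      mat[ids2, col] <- .fixed_column(length(ids2), b, eps)
      mat[ids1, col] <- sample(AA20, length(ids1), replace = TRUE)
      truth$res_b[k] <- b
    } else {
      a <- sample(AA20, 1L)
      mat[ids1, col] <- .fixed_column(length(ids1), a, eps)
      mat[ids2, col] <- sample(AA20, length(ids2), replace = TRUE)
      truth$res_a[k] <- a
    }
  }
  out <- clade_msa(msa$ids, apply(mat[msa$ids, , drop = FALSE], 1L,
                                  paste, collapse = ""),
                   msa$clades, clade_levels = msa$clade_levels)
  truth <- truth[order(truth$column), , drop = FALSE]
  rownames(truth) <- NULL
  list(msa = out, truth = truth)
}

#' Kyte-Doolittle hydropathy index
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Amino-acid side-chain volumes (cubic angstrom)
#' @return Named numeric vector over the 20 amino acids.
#' @export
residue_volumes <- function() {
  c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
    H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
    P = 112.7, Q = 143.8, R = 173.4, S = 89.0, T = 116.1, V = 140.0,
    W = 227.8, Y = 193.6)
}

#' Surrogate ddG substitution matrix from a physicochemical heuristic
#'
#' Stands in for a force-field position scan when none is available. The
#' stability effect of mutating wild-type residue `w` to residue `a` is
#' \deqn{0.4\,|KD(a) - KD(w)| + 1.5\,\frac{|V(a) - V(w)|}{V_{max}} +
#'       N(0, 0.1^2)}
#' in kcal/mol, where KD is the Kyte-Doolittle hydropathy and V the
#' residue volume; the diagonal (a = w) is exactly 0. Bigger
#' physicochemical jumps cost more, which is all the downstream statistic
#' needs.
#'
#' @param wt_seq the structure's wild-type amino-acid sequence (string or
#'   character vector; position `i` of the matrix is residue `i`).
#' @param seed integer seed for the noise.
#' @param noise_sd gaussian noise sd in kcal/mol (default 0.1; 0 gives
#'   the deterministic heuristic).
#' @return A [ddg_matrix()] with one row per sequence position.
#' @export
surrogate_ddg <- function(wt_seq, seed = 1, noise_sd = 0.1) {
  s <- if (length(wt_seq) == 1L)
    strsplit(toupper(wt_seq), "", fixed = TRUE)[[1]] else toupper(wt_seq)
  if (any(!s %in% AA20))
    stop("wild-type sequence must contain only the 20 amino acids")
  set.seed(seed)
  kd <- kyte_doolittle(); vol <- residue_volumes()
  vmax <- max(vol)
  n <- length(s)
  base <- matrix(0, nrow = n, ncol = 20L, dimnames = list(NULL, AA20))
  for (a in AA20)
    base[, a] <- 0.4 * abs(kd[a] - kd[s]) +
      1.5 * abs(vol[a] - vol[s]) / vmax
  noise <- matrix(stats::rnorm(n * 20L, 0, noise_sd), nrow = n)
  m <- base + noise
  m[cbind(seq_len(n), match(s, AA20))] <- 0
  df <- data.frame(position = seq_len(n), wt = s, stringsAsFactors = FALSE)
  for (a in AA20) df[[a]] <- m[, a]
  ddg_matrix(df)
}

#' Toy two-helix structure with a pseudo-ligand
#'
#' Two ideal poly-alanine alpha-helices (CA trace of radius 2.3 angstrom,
#' rise 1.5 angstrom/residue, 100 degrees/residue, plus an outward CB at
#' radius 3.4) along parallel axes, as chains A and B. `separation` is the
#' gap between the CA envelopes of the two helices, so the closest CA-CA
#' approach is about `separation`. A three-heavy-atom pseudo-ligand (NAG)
#' is placed radially outward at `ligand_offset` angstrom from the CA of
#' chain A residue `ligand_residue`. Coordinates are deterministic.
#'
#' @param n_res residues per chain (>= 2).
#' @param separation inter-helix surface gap, angstrom.
#' @param ligand_offset distance from the anchor CA to the nearest ligand
#'   atom, angstrom.
#' @param ligand_residue anchor residue number on chain A.
#' @param path optional PDB output path; when given the file is written.
#' @return A `struct_model` (invisibly also written to `path` if given).
#' @export
toy_structure <- function(n_res = 20, separation = 8,
                          ligand_offset = 3, ligand_residue = 10,
                          path = NULL) {
  if (n_res < 2) stop("need at least 2 residues per chain")
  if (ligand_residue < 1 || ligand_residue > n_res)
    stop("ligand_residue outside chain A")
  helix <- function(shift_x) {
    i <- seq_len(n_res)
    theta <- (i - 1) * 100 * pi / 180
    data.frame(resno = rep(i, each = 2L),
               elety = rep(c("CA", "CB"), n_res),
               x = shift_x + rep(c(2.3, 3.4), n_res) *
                 cos(rep(theta, each = 2L)),
               y = rep(c(2.3, 3.4), n_res) * sin(rep(theta, each = 2L)),
               z = rep((i - 1) * 1.5, each = 2L))
  }
  a <- cbind(chain = "A", helix(0))
  b <- cbind(chain = "B", helix(separation + 2 * 2.3))
  prot <- rbind(a, b)
  # ligand: placed radially outward from the anchor CA so its nearest
  # protein atoms belong to the anchor residue
  th <- (ligand_residue - 1) * 100 * pi / 180
  u <- c(cos(th), sin(th), 0)
  ca <- c(2.3 * cos(th), 2.3 * sin(th), (ligand_residue - 1) * 1.5)
  lig <- t(vapply(c(0, 0.9, 1.8), function(extra) ca +
                    (ligand_offset + extra) * u, numeric(3)))
  atoms <- data.frame(
    type = c(rep("ATOM", nrow(prot)), rep("HETATM", 3L)),
    elety = c(prot$elety, c("C1", "C2", "O5")),
    resid = c(rep("ALA", nrow(prot)), rep("NAG", 3L)),
    chain = c(prot$chain, rep("L", 3L)),
    resno = c(prot$resno, rep(1L, 3L)),
    insert = "",
    x = c(prot$x, lig[, 1]), y = c(prot$y, lig[, 2]),
    z = c(prot$z, lig[, 3]),
    o = 1, elesy = c(substr(prot$elety, 1L, 1L), "C", "C", "O"),
    stringsAsFactors = FALSE)
  st <- structure(list(atoms = atoms, ligands = "NAG"),
                  class = "struct_model")
  if (!is.null(path)) write_structure(st, path)
  st
}

#' Write a structure model to PDB
#' @param struct a `struct_model`.
#' @param path output PDB path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(struct, path) {
  at <- struct$atoms
  bio3d::write.pdb(file = path, type = at$type, xyz = as.numeric(t(
    as.matrix(at[, c("x", "y", "z")]))), resno = at$resno,
    chain = at$chain, resid = at$resid, elety = at$elety, o = at$o,
    elesy = at$elesy)
  invisible(path)
}

#' Write a full synthetic input bundle
#'
#' Emits every file the pipeline stages read: aligned FASTA + clade TSV,
#' the generating Newick tree, the planted-site truth table, a surrogate
#' ddG matrix for the first sequence of the first clade, and a toy PDB.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @param labels clade labels.
#' @return Invisibly, a named list of the paths written.
#' @export
write_synthetic_bundle <- function(spec, dir,
                                   labels = c("cladeA", "cladeB")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msa <- simulate_null_alignment(spec, labels)
  truth <- NULL
  if (sum(spec$plan) > 0) {
    pl <- plant_divergent_sites(msa, spec$plan, spec$eps,
                                seed = spec$seed + 1L)
    tree <- attr(msa, "tree")
    msa <- pl$msa
    attr(msa, "tree") <- tree
    truth <- pl$truth
  }
  paths <- list(msa = file.path(dir, "msa.fasta"),
                clades = file.path(dir, "clades.tsv"),
                tree = file.path(dir, "tree.nwk"),
                truth = file.path(dir, "truth.tsv"),
                ddg = file.path(dir, "ddg.tsv"),
                pdb = file.path(dir, "structure.pdb"))
  write_clade_msa(msa, paths$msa, paths$clades)
  ape::write.tree(attr(msa, "tree"), paths$tree)
  if (is.null(truth))
    truth <- data.frame(column = integer(0), type = character(0),
                        res_a = character(0), res_b = character(0))
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ref <- clade_ids(msa, msa$clade_levels[1])[1]
  wt <- gsub("-", "", unname(msa$seqs[ref]), fixed = TRUE)
  write_ddg_matrix(surrogate_ddg(wt, seed = spec$seed), paths$ddg)
  toy_structure(n_res = min(50L, nchar(wt)), path = paths$pdb)
  invisible(paths)
}
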