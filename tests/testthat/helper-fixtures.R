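# Shared fixtures and independent oracles, all built in code.

# tiny deterministic two-clade alignment
tiny_msa <- function() {
  clade_msa(ids = c("g1", "g2", "g3", "g4", "p1", "p2", "p3", "p4"),
            seqs = c("ACDEF-", "ACDEG-", "ACDEH-", "ACDEI-",
                     "QCDKFW", "QCDKGW", "QCDKHW", "QCDKIW"),
            clades = c(g1 = "G", g2 = "G", g3 = "G", g4 = "G",
                       p1 = "P", p2 = "P", p3 = "P", p4 = "P"),
            clade_levels = c("G", "P"))
}

# random valid alignment for property tests
random_msa <- function(n_per_clade = 5, n_col = 30, seed = 1,
                       gap_prob = 0.1) {
  set.seed(seed)
  n <- 2 * n_per_clade
  chars <- matrix(sample(c(AA20, "-", "X"), n * n_col, replace = TRUE,
                         prob = c(rep((1 - gap_prob) / 20, 20),
                                  gap_prob * 0.7, gap_prob * 0.3)),
                  nrow = n)
  ids <- c(paste0("a", seq_len(n_per_clade)),
           paste0("b", seq_len(n_per_clade)))
  clade_msa(ids, apply(chars, 1, paste, collapse = ""),
            stats::setNames(rep(c("A", "B"), each = n_per_clade), ids),
            clade_levels = c("A", "B"))
}

# brute-force conservation oracle: recount the column composition from
# scratch, never sharing code with the package internals
oracle_conservation <- function(residues, min_count = 4) {
  obs <- residues[!(residues %in% c("-", "X"))]
  if (length(obs) < min_count) return(NA_real_)
  freqs <- sapply(unique(obs), function(a) sum(obs == a)) / length(obs)
  1 - (-sum(freqs * log(freqs))) / log(20)
}

oracle_modal <- function(residues) {
  obs <- residues[!(residues %in% c("-", "X"))]
  counts <- sapply(sort(unique(obs)), function(a) sum(obs == a))
  names(counts)[which.max(counts)]
}

# all-pairs brute-force minimum heavy-atom distance per residue of set a
oracle_min_dists <- function(atoms_a, atoms_b) {
  keys <- unique(paste(atoms_a$chain, atoms_a$resno, atoms_a$insert,
                       sep = "|"))
  sapply(keys, function(k) {
    sel <- paste(atoms_a$chain, atoms_a$resno, atoms_a$insert,
                 sep = "|") == k
    best <- Inf
    for (i in which(sel)) for (j in seq_len(nrow(atoms_b))) {
      d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
                (atoms_a$y[i] - atoms_b$y[j])^2 +
                (atoms_a$z[i] - atoms_b$z[j])^2)
      if (d < best) best <- d
    }
    best
  })
}

# patristic-distance oracle: path enumeration from each tip to the root,
# then join at the deepest shared node
oracle_patristic <- function(tree, a, b) {
  path_to_root <- function(tip) {
    node <- match(tip, tree$tip.label)
    path <- node
    lens <- numeric(0)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      lens <- c(lens, tree$edge.length[e])
      node <- tree$edge[e, 1]
      path <- c(path, node)
    }
    list(path = path, lens = lens)
  }
  pa <- path_to_root(a); pb <- path_to_root(b)
  shared <- intersect(pa$path, pb$path)
  mrca <- shared[1]  # first shared node walking up from a
  ia <- match(mrca, pa$path); ib <- match(mrca, pb$path)
  sum(pa$lens[seq_len(ia - 1)]) + sum(pb$lens[seq_len(ib - 1)])
}

# minimal in-code structure: residues given as list of atom data frames
make_struct <- function(atoms) {
  structure(list(atoms = atoms,
                 ligands = unique(atoms$resid[atoms$type == "HETATM"])),
            class = "struct_model")
}

atom_row <- function(type, elety, resid, chain, resno, x, y, z) {
  data.frame(type = type, elety = elety, resid = resid, chain = chain,
             resno = resno, insert = "", x = x, y = y, z = z, o = 1,
             elesy = substr(elety, 1, 1), stringsAsFactors = FALSE)
}
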