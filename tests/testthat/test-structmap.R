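test_that("PDB write/read round-trips the toy structure", {
  path <- tempfile(fileext = ".pdb")
  toy_structure(n_res = 12, separation = 5, ligand_offset = 3,
                ligand_residue = 4, path = path)
  st <- read_structure(path)
  expect_setequal(unique(st$atoms$chain[st$atoms$type == "ATOM"]),
                  c("A", "B"))
  expect_true("NAG" %in% st$ligands)
  expect_equal(sum(st$atoms$resid == "NAG"), 3L)

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), "atoms")
  expect_error(read_structure("/nonexistent.pdb"), "no such file")
  unlink(c(path, empty))
})

test_that("hydrogens, waters and low-occupancy altlocs are dropped", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  H   ALA A   1       1.000   0.000   0.000  1.00 10.00           H",
    "ATOM      4  CA  GLY A   2       3.000   0.000   0.000  1.00 10.00           C",
    "HETATM    5  O   HOH A 101       9.000   0.000   0.000  1.00 10.00           O",
    "END"), path)
  st <- read_structure(path)
  # one CA kept for residue 1, at the higher-occupancy position
  r1 <- st$atoms[st$atoms$resno == 1, ]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$x, 5.0)
  expect_false(any(st$atoms$resid == "HOH"))
  expect_false(any(grepl("^H", st$atoms$elety)))
  unlink(path)
})

test_that("interface detection uses a strict cutoff", {
  atoms <- rbind(atom_row("ATOM", "CA", "ALA", "A", 1, 0, 0, 0),
                 atom_row("ATOM", "CA", "ALA", "B", 1, 5, 0, 0),
                 atom_row("ATOM", "CA", "ALA", "B", 2, 6, 0, 0))
  st <- make_struct(atoms)
  cs <- interface_residues(st, "A", "B", cutoff = 6)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$min_dist, 5.0)

  # a residue exactly at the cutoff is NOT a contact
  st2 <- make_struct(atoms[c(1, 3), ])
  expect_equal(nrow(interface_residues(st2, "A", "B", cutoff = 6)), 0L)
  expect_equal(nrow(interface_residues(st2, "A", "B", cutoff = 6.0001)),
               1L)
  expect_error(interface_residues(st, "A", "C"), "missing chain")
})

test_that("toy-helix contact sets equal the brute-force oracle", {
  st <- toy_structure(n_res = 20, separation = 4, ligand_offset = 3,
                      ligand_residue = 10)
  at <- st$atoms
  a <- at[at$type == "ATOM" & at$chain == "A", ]
  b <- at[at$type == "ATOM" & at$chain == "B", ]
  for (cutoff in c(5, 6, 8)) {
    cs <- interface_residues(st, "A", "B", cutoff)
    oracle <- oracle_min_dists(a, b)
    expect_setequal(cs$resno, a$resno[!duplicated(a$resno)][
      oracle < cutoff])
    expect_equal(sort(cs$min_dist), sort(unname(oracle[oracle < cutoff])),
                 tolerance = 1e-9)
  }
  # symmetry: the closest approach is the same from both sides
  ab <- interface_residues(st, "A", "B", 8)
  ba <- interface_residues(st, "B", "A", 8)
  expect_equal(min(ab$min_dist), min(ba$min_dist), tolerance = 1e-9)
  # monotone growth with the cutoff
  expect_true(all(interface_residues(st, "A", "B", 5)$resno %in%
                  interface_residues(st, "A", "B", 6)$resno))
  expect_true(all(interface_residues(st, "A", "B", 6)$resno %in%
                  interface_residues(st, "A", "B", 8)$resno))
})

test_that("ligand proximity finds the anchored residue and respects range", {
  st <- toy_structure(n_res = 20, separation = 8, ligand_offset = 3,
                      ligand_residue = 10)
  lp <- ligand_proximal_residues(st, "NAG", 6)
  expect_true(10 %in% lp$resno)

  far <- toy_structure(n_res = 20, separation = 8, ligand_offset = 50,
                       ligand_residue = 10)
  expect_equal(nrow(ligand_proximal_residues(far, "NAG", 6)), 0L)
  expect_error(ligand_proximal_residues(st, "XYZ"), "ligand absent")

  # oracle agreement
  at <- st$atoms
  prot <- at[at$type == "ATOM", ]
  lig <- at[at$type == "HETATM" & at$resid == "NAG", ]
  oracle <- oracle_min_dists(prot, lig)
  keys <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
  expect_setequal(paste(lp$chain, lp$resno, lp$insert, sep = "|"),
                  unique(keys)[oracle < 6])
})

test_that("sequon scanning matches the N-X-S/T consensus", {
  expect_equal(scan_sequons("NAT")$position, 1L)
  expect_equal(nrow(scan_sequons("QAT")), 0L)
  expect_equal(scan_sequons("NAT")$triplet, "NAT")
  # overlapping sequons are all reported
  expect_equal(scan_sequons("NNSS")$position, c(1L, 2L))
  # proline exclusion is off by default
  expect_equal(scan_sequons("NPT")$position, 1L)
  expect_equal(nrow(scan_sequons("NPT", exclude_proline = TRUE)), 0L)
  expect_equal(nrow(scan_sequons("NA")), 0L)
})

test_that("sequon scanner equals a lookahead-regex oracle", {
  set.seed(31)
  for (i in 1:1000) {
    s <- paste(sample(AA20, sample(3:30, 1), replace = TRUE),
               collapse = "")
    hits <- scan_sequons(s)$position
    m <- gregexpr("N(?=.[ST])", s, perl = TRUE)[[1]]
    oracle <- if (m[1] == -1) integer(0) else as.integer(m)
    # the oracle also matches N at the last two positions; restrict
    oracle <- oracle[oracle <= nchar(s) - 2]
    expect_equal(hits, oracle)
  }
})

test_that("the paralog sequon gain/loss worked example reproduces", {
  # synthetic fragments copying the divergent residues: the GAS6-like
  # sequence has N at 463 and T at 465 (an intact N-x-T sequon); the
  # PROS1-like sequence has K and Y at the aligned positions, which
  # breaks the motif
  gas6_frag <- "GLNLTEV"   # positions 461..467
  pros1_frag <- "GLKLYEV"  # aligned positions 422..428
  hits_g <- scan_sequons(gas6_frag, numbering = 461:467)
  expect_true(463 %in% hits_g$position)
  expect_equal(hits_g$triplet[hits_g$position == 463], "NLT")
  hits_p <- scan_sequons(pros1_frag, numbering = 422:428)
  expect_equal(nrow(hits_p), 0L)
})

test_that("sites map onto chain residues through alignment", {
  # reference sequence of 30 residues; the chain models residues 5..24
  # but is missing an internal loop (11..14)
  set.seed(17)
  ref <- paste(sample(AA20, 30, replace = TRUE), collapse = "")
  modelled <- c(5:10, 15:24)
  chars <- strsplit(ref, "")[[1]]
  atoms <- do.call(rbind, lapply(seq_along(modelled), function(i) {
    r <- modelled[i]
    atom_row("ATOM", "CA", bio3d::aa123(chars[r]), "A", r,
             i * 3.8, 0, 0)
  }))
  st <- make_struct(atoms)

  ids <- paste0("s", 1:8)
  msa <- clade_msa(ids, rep(ref, 8),
                   stats::setNames(rep(c("G", "P"), each = 4), ids),
                   clade_levels = c("G", "P"))
  sites <- structure(data.frame(
    aln_col = c(7L, 12L, 20L, 28L),
    gas6_pos1 = NA_integer_, gas6_pos2 = NA_integer_,
    gas6_aa = chars[c(7, 12, 20, 28)],
    pros1_pos = NA_integer_, pros1_aa = chars[c(7, 12, 20, 28)],
    methods = "II", stringsAsFactors = FALSE),
    class = c("site_table", "data.frame"))
  ann <- map_sites_to_structure(sites, msa, "s1", st, "A")
  expect_equal(ann$mapped, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ann$resno[ann$mapped], c(7L, 20L))

  # brute-force join: mapped iff the residue was modelled
  expect_equal(ann$mapped, sites$aln_col %in% modelled)
})
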