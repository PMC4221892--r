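test_that("clade conservation matches direct entropy arithmetic", {
  mono <- clade_conservation(rep("A", 15))
  expect_equal(mono$c, 1.0)
  expect_equal(mono$modal, "A")

  distinct <- clade_conservation(AA20[1:15])
  expect_equal(distinct$c, 1 - log(15) / log(20), tolerance = 1e-12)

  mixed <- clade_conservation(c(rep("A", 10), rep("V", 5)))
  H <- -((2 / 3) * log(2 / 3) + (1 / 3) * log(1 / 3))
  expect_equal(mixed$c, 1 - H / log(20), tolerance = 1e-12)
  expect_equal(mixed$modal, "A")

  # modal ties break to the lexicographically smallest residue
  tie <- clade_conservation(c("V", "V", "C", "C", "A"))
  expect_equal(tie$modal, "C")

  # gaps/X excluded; below the minimum effective count the column is masked
  masked <- clade_conservation(c("A", "A", "X", "-", "-"))
  expect_true(is.na(masked$c))
  expect_equal(masked$n_eff, 2L)
})

test_that("vectorised scores equal a brute-force per-column recount", {
  for (seed in 1:4) {
    msa <- random_msa(n_per_clade = 6, n_col = 40, seed = seed)
    sc <- divergence_scores(msa)
    mat <- as.matrix(msa)
    for (col in seq_len(msa$n_columns)) {
      c1 <- oracle_conservation(mat[clade_ids(msa, "A"), col])
      c2 <- oracle_conservation(mat[clade_ids(msa, "B"), col])
      if (is.na(c1) || is.na(c2)) {
        expect_true(is.na(sc$s_ia[col]) && is.na(sc$s_ib[col]))
      } else {
        m1 <- oracle_modal(mat[clade_ids(msa, "A"), col])
        m2 <- oracle_modal(mat[clade_ids(msa, "B"), col])
        expect_equal(sc$s_ia[col], c2 * (1 - c1), tolerance = 1e-12)
        expect_equal(sc$s_ib[col], c1 * (1 - c2), tolerance = 1e-12)
        expect_equal(sc$s_ii[col], c1 * c2 * (m1 != m2),
                     tolerance = 1e-12)
        expect_equal(sc$modal_1[col], m1)
      }
    }
  }
})

test_that("score definitions express the Type Ia/Ib/II patterns", {
  # both clades fixed, same residue: nothing diverges
  m0 <- clade_msa(paste0("s", 1:8), rep("AAAA", 8),
                  stats::setNames(rep(c("G", "P"), each = 4),
                                  paste0("s", 1:8)),
                  clade_levels = c("G", "P"))
  sc0 <- divergence_scores(m0)
  expect_true(all(sc0$s_ia == 0 & sc0$s_ib == 0 & sc0$s_ii == 0))

  # conserved-but-different (the E/Q pattern): pure Type II, score 1
  m2 <- clade_msa(paste0("s", 1:8),
                  c(rep("EEEE", 4), rep("QQQQ", 4)),
                  stats::setNames(rep(c("G", "P"), each = 4),
                                  paste0("s", 1:8)),
                  clade_levels = c("G", "P"))
  sc2 <- divergence_scores(m2)
  expect_true(all(sc2$s_ii == 1))
  expect_true(all(sc2$s_ia == 0 & sc2$s_ib == 0))

  # second clade conserved, first variable, same modal residue:
  # S_Ia = c_P (1 - c_G), S_II = 0
  m1 <- clade_msa(paste0("s", 1:8),
                  c("A", "A", "C", "D", "A", "A", "A", "A"),
                  stats::setNames(rep(c("G", "P"), each = 4),
                                  paste0("s", 1:8)),
                  clade_levels = c("G", "P"))
  sc1 <- divergence_scores(m1)
  cg <- oracle_conservation(c("A", "A", "C", "D"))
  expect_equal(sc1$s_ia, 1 * (1 - cg), tolerance = 1e-12)
  expect_equal(sc1$s_ib, cg * 0, tolerance = 1e-12)
  expect_equal(sc1$s_ii, 0)
})

test_that("swapping clade labels swaps S_Ia and S_Ib, fixes S_II", {
  msa <- random_msa(n_per_clade = 6, n_col = 50, seed = 11)
  swapped <- clade_msa(msa$ids, msa$seqs, msa$clades,
                       clade_levels = rev(msa$clade_levels))
  a <- divergence_scores(msa)
  b <- divergence_scores(swapped)
  expect_equal(a$s_ia, b$s_ib)
  expect_equal(a$s_ib, b$s_ia)
  expect_equal(a$s_ii, b$s_ii)
})

test_that("threshold calibration is the empirical percentile", {
  expect_equal(calibrate_threshold(rep(0, 200))$cutoff, 0)
  expect_equal(calibrate_threshold(rep(c(0, 1), 100),
                                   percentile = 50)$cutoff, 0.5)

  set.seed(42)
  u <- runif(1000)
  th <- calibrate_threshold(u, 99)
  expect_equal(th$cutoff, 0.99, tolerance = 0.01)
  expect_equal(th$n_null, 1000L)

  # monotone in the percentile
  cuts <- vapply(c(50, 90, 95, 99),
                 function(p) calibrate_threshold(u, p)$cutoff, numeric(1))
  expect_true(all(diff(cuts) >= 0))

  expect_error(calibrate_threshold(runif(50)), "too few")
  expect_error(calibrate_threshold(u, 0), "percentile")
})

test_that("planted perfect Type II columns are always detected", {
  null_msa <- simulate_null_alignment(sim_spec(n_columns = 1500,
                                               seed = 5))
  th <- calibrate_thresholds(null_msa)
  expect_true(th$II$cutoff < 1)

  base <- simulate_null_alignment(sim_spec(n_columns = 300, seed = 6))
  pl <- plant_divergent_sites(base, c(II = 10), eps = 0, seed = 7)
  det <- detect_sites(pl$msa, th, jackknife = FALSE)
  hit <- det$aln_col[grepl("II", det$methods)]
  expect_true(all(pl$truth$column %in% hit))
})

test_that("columns masked in every replicate are never flagged", {
  # one clade all-X at column 2: unscoreable everywhere
  seqs <- c(rep("AXAA", 4), rep("CECE", 4))
  msa <- clade_msa(paste0("s", 1:8), seqs,
                   stats::setNames(rep(c("G", "P"), each = 4),
                                   paste0("s", 1:8)),
                   clade_levels = c("G", "P"))
  det <- detect_sites(msa, list(Ia = 0.1, Ib = 0.1, II = 0.1),
                      jackknife = TRUE)
  expect_false(2L %in% det$aln_col)
})

test_that("jackknife detection recovers sites degraded by one sequence", {
  # a Type II column with one deviant residue in clade G: the full
  # alignment scores 0.833 (below cutoff 0.9) but the replicate dropping
  # the deviant sequence scores 1; the union retains the detection
  seqs <- c("CA", "AA", "AA", "AA", "AA",
            "DA", "DA", "DA", "DA", "DA")
  ids <- paste0("s", 1:10)
  msa <- clade_msa(ids, seqs,
                   stats::setNames(rep(c("G", "P"), each = 5), ids),
                   clade_levels = c("G", "P"))
  th <- list(Ia = 0.9, Ib = 0.9, II = 0.9)
  no_jack <- detect_sites(msa, th, jackknife = FALSE)
  expect_false(1L %in% no_jack$aln_col)
  jack <- detect_sites(msa, th, jackknife = TRUE)
  expect_true(1L %in% jack$aln_col)
  expect_match(jack$methods[jack$aln_col == 1L], "II")
})

test_that("external results merge by union at the posterior threshold", {
  internal <- detect_sites(
    clade_msa(paste0("s", 1:8),
              c(rep("EA", 4), rep("QA", 4)),
              stats::setNames(rep(c("G", "P"), each = 4),
                              paste0("s", 1:8)),
              clade_levels = c("G", "P")),
    list(Ia = 0.9, Ib = 0.9, II = 0.9), jackknife = FALSE)
  expect_equal(internal$aln_col, 1L)
  expect_equal(internal$methods, "II")

  fd <- external_result("FD",
                        data.frame(aln_col = c(1L, 2L),
                                   statistic = c(0.96, 0.90)))
  merged <- merge_method_results(internal, list(fd))
  # 0.96 >= 0.95 retained (tag joins column 1); 0.90 dropped (no column 2)
  expect_equal(merged$aln_col, 1L)
  expect_equal(merged$methods, "FD,II")

  # disjoint external site concatenates
  ps <- external_result("PS", data.frame(aln_col = 2L, statistic = 0.99))
  merged2 <- merge_method_results(internal, list(fd, ps))
  expect_equal(merged2$aln_col, c(1L, 2L))
  expect_equal(merged2$methods[2], "PS")

  expect_error(external_result("FD",
                               data.frame(aln_col = 1, statistic = 1.2)),
               "\\[0, 1\\]")
})

test_that("conflicting residue annotations abort a merge", {
  a <- detect_sites(
    clade_msa(paste0("s", 1:8), c(rep("E", 4), rep("Q", 4)),
              stats::setNames(rep(c("G", "P"), each = 4),
                              paste0("s", 1:8)),
              clade_levels = c("G", "P")),
    list(Ia = 0.9, Ib = 0.9, II = 0.9), jackknife = FALSE)
  b <- a
  b$gas6_aa <- "W"
  expect_error(merge_method_results(rbind(a, b)), "consistency error")
})
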