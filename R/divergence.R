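# Per-column Type Ia / Ib / II divergence scores, null-calibrated
# percentile thresholds, jackknife detection and method merging.
#
# Type I: a column conserved in one clade but variable in the other
#   (Ia: conserved in the second clade, divergent in the first;
#    Ib: conserved in the first clade, divergent in the second).
# Type II: conserved in both clades, but for different residues.

#' Conservation of one clade at one alignment column
#'
#' Conservation is `1 - H / ln(20)` where `H` is the Shannon entropy
#' (natural log) of the amino-acid frequencies among non-missing residues
#' (gaps and `X` excluded). `c = 1` iff exactly one residue type is
#' observed; the score is masked (`NA`) when fewer than `min_count`
#' scoreable residues remain, preventing spurious perfect conservation from
#' tiny samples.
#'
#' @param residues character vector of single residues (one clade, one
#'   column); `-` and `X` are ignored.
#' @param min_count minimum effective (non-missing) count; default 4.
#' @return list with `c` (conservation in \[0,1\] or `NA`), `modal` (most
#'   frequent residue, ties broken to the lexicographically smallest; `NA`
#'   when masked) and `n_eff` (effective count).
#' @export
clade_conservation <- function(residues, min_count = 4) {
  obs <- residues[residues %in% AA20]
  n <- length(obs)
  if (n < min_count)
    return(list(c = NA_real_, modal = NA_character_, n_eff = n))
  counts <- table(factor(obs, levels = AA20))
  p <- counts[counts > 0] / n
  H <- -sum(p * log(p))
  # table over AA20 is lexicographically ordered, so which.max takes the
  # smallest residue on ties
  list(c = 1 - H / log(20),
       modal = AA20[which.max(counts)],
       n_eff = n)
}

# Vectorised conservation over all columns of a character matrix
# (rows = sequences of one clade). Returns list of vectors c, modal, n_eff.
.profile_matrix <- function(mat, min_count = 4) {
  ncol_aln <- ncol(mat)
  counts <- matrix(0L, nrow = 20L, ncol = ncol_aln,
                   dimnames = list(AA20, NULL))
  for (i in seq_along(AA20))
    counts[i, ] <- .colSums(mat == AA20[i], nrow(mat), ncol_aln)
  n_eff <- .colSums(counts, 20L, ncol_aln)
  p <- sweep(counts, 2L, pmax(n_eff, 1L), "/")
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  H <- -.colSums(plogp, 20L, ncol_aln)
  cons <- 1 - H / log(20)
  modal <- AA20[apply(counts, 2L, which.max)]  # first max = lexicographic
  masked <- n_eff < min_count
  cons[masked] <- NA_real_
  modal[masked] <- NA_character_
  list(c = cons, modal = modal, n_eff = as.integer(n_eff))
}

#' Per-clade conservation profile for every column
#'
#' @param msa a [clade_msa()].
#' @param min_count minimum effective residues per clade per column.
#' @return data frame with one row per column: `column`, then for each clade
#'   (in `msa$clade_levels` order, suffixes `_1` and `_2`) the conservation
#'   `c`, modal residue and effective count.
#' @export
conservation_profile <- function(msa, min_count = 4) {
  mat <- as.matrix(msa)
  p1 <- .profile_matrix(mat[clade_ids(msa, msa$clade_levels[1]), ,
                            drop = FALSE], min_count)
  p2 <- .profile_matrix(mat[clade_ids(msa, msa$clade_levels[2]), ,
                            drop = FALSE], min_count)
  data.frame(column = seq_len(msa$n_columns),
             c_1 = p1$c, modal_1 = p1$modal, n_eff_1 = p1$n_eff,
             c_2 = p2$c, modal_2 = p2$modal, n_eff_2 = p2$n_eff,
             stringsAsFactors = FALSE)
}

#' Type Ia / Ib / II divergence scores for every alignment column
#'
#' With clade conservations `c1` (first clade, GAS6 role) and `c2` (second
#' clade, PROS1 role) and modal residues `m1`, `m2`:
#' \deqn{S_{Ia} = c_2 (1 - c_1), \quad S_{Ib} = c_1 (1 - c_2), \quad
#'       S_{II} = c_1 c_2 \, [m_1 \neq m_2]}
#' All scores lie in \[0,1\]. `S_II` is 0 whenever the modal residues
#' coincide. Columns masked in either clade get `NA` scores.
#'
#' @inheritParams conservation_profile
#' @param columns optional integer vector restricting the columns returned.
#' @return data frame: `column`, `c_1`, `modal_1`, `c_2`, `modal_2`,
#'   `s_ia`, `s_ib`, `s_ii`.
#' @export
divergence_scores <- function(msa, columns = NULL, min_count = 4) {
  prof <- conservation_profile(msa, min_count = min_count)
  s_ia <- prof$c_2 * (1 - prof$c_1)
  s_ib <- prof$c_1 * (1 - prof$c_2)
  s_ii <- prof$c_1 * prof$c_2 *
    as.numeric(prof$modal_1 != prof$modal_2)
  out <- data.frame(column = prof$column,
                    c_1 = prof$c_1, modal_1 = prof$modal_1,
                    c_2 = prof$c_2, modal_2 = prof$modal_2,
                    s_ia = s_ia, s_ib = s_ib, s_ii = s_ii,
                    stringsAsFactors = FALSE)
  if (!is.null(columns)) out <- out[out$column %in% columns, , drop = FALSE]
  out
}

#' Calibrate a detection threshold on null scores
#'
#' The cutoff is the empirical `percentile`-th percentile (linear
#' interpolation between order statistics, [stats::quantile()] type 7) of
#' scores computed on simulated null alignments. At the default 99th
#' percentile the detector tolerates a 1% false-positive rate per score
#' type on null data.
#'
#' @param null_scores numeric vector of at least 100 null scores (`NA`
#'   dropped).
#' @param percentile percentile in (0, 100); default 99.
#' @param score_type optional label ("Ia", "Ib" or "II").
#' @return A `calibrated_threshold`: list with `score_type`, `percentile`,
#'   `cutoff`, `n_null` and the null sample itself.
#' @export
calibrate_threshold <- function(null_scores, percentile = 99,
                                score_type = NA_character_) {
  null_scores <- null_scores[!is.na(null_scores)]
  if (length(null_scores) < 100L)
    stop("too few null scores (", length(null_scores), " < 100)")
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  cutoff <- unname(stats::quantile(null_scores, percentile / 100,
                                   type = 7, names = FALSE))
  structure(list(score_type = score_type, percentile = percentile,
                 cutoff = cutoff, n_null = length(null_scores),
                 null_scores = null_scores),
            class = "calibrated_threshold")
}

#' @export
print.calibrated_threshold <- function(x, ...) {
  cat(sprintf("calibrated_threshold [%s]: %gth percentile of %d null scores = %.6g\n",
              x$score_type, x$percentile, x$n_null, x$cutoff))
  invisible(x)
}

#' Calibrate Ia/Ib/II thresholds from a null alignment
#'
#' Convenience wrapper: scores every column of a simulated null alignment
#' and calibrates one threshold per score type at the same percentile.
#'
#' @param null_msa a null [clade_msa()] (see [simulate_null_alignment()]).
#' @param percentile percentile, default 99.
#' @param min_count per-clade column masking threshold.
#' @return named list of three `calibrated_threshold`s: `Ia`, `Ib`, `II`.
#' @export
calibrate_thresholds <- function(null_msa, percentile = 99, min_count = 4) {
  sc <- divergence_scores(null_msa, min_count = min_count)
  out <- list(Ia = calibrate_threshold(sc$s_ia, percentile, "Ia"),
              Ib = calibrate_threshold(sc$s_ib, percentile, "Ib"),
              II = calibrate_threshold(sc$s_ii, percentile, "II"))
  for (t in out) {
    # scores are bounded by 1; a cutoff at the bound cannot be exceeded,
    # which happens when the null tree's clades are so shallow that >1% of
    # null columns are perfectly conserved (for different residues)
    if (t$cutoff >= 1)
      warning("the ", t$score_type, " cutoff reached the score upper ",
              "bound (1): no column can exceed it; the null conditions ",
              "are too shallow for percentile calibration at ",
              percentile, "%", call. = FALSE)
  }
  out
}

.check_thresholds <- function(thresholds) {
  if (!all(c("Ia", "Ib", "II") %in% names(thresholds)))
    stop("thresholds must be a named list with elements Ia, Ib and II")
  vapply(thresholds[c("Ia", "Ib", "II")],
         function(t) if (inherits(t, "calibrated_threshold")) t$cutoff
                     else as.numeric(t),
         numeric(1))
}

#' Detect functionally divergent sites
#'
#' A column is flagged with tag `Ia`, `Ib` or `II` if its score strictly
#' exceeds the calibrated cutoff for that type in the full alignment or in
#' any leave-one-out jackknife replicate (union over replicates — every
#' detection is retained). The jackknife recovers columns that are masked
#' or degraded in the full alignment by a single gappy/ambiguous sequence.
#'
#' @param msa a [clade_msa()].
#' @param thresholds named list (`Ia`, `Ib`, `II`) of
#'   `calibrated_threshold`s (or bare numeric cutoffs).
#' @param jackknife logical; also scan all leave-one-out replicates
#'   (default `TRUE`).
#' @param min_count per-clade column masking threshold.
#' @return A `site_table` with one row per flagged column: `aln_col`, the
#'   clade modal residues (from the full alignment) as `gas6_aa` /
#'   `pros1_aa`, positions `NA`, and `methods` = comma-joined tags.
#' @export
detect_sites <- function(msa, thresholds, jackknife = TRUE, min_count = 4) {
  cut <- .check_thresholds(thresholds)
  batches <- list(divergence_scores(msa, min_count = min_count))
  if (jackknife)
    batches <- c(batches,
                 lapply(jackknife_alignments(msa), divergence_scores,
                        min_count = min_count))
  nc <- msa$n_columns
  hit <- matrix(FALSE, nrow = nc, ncol = 3L,
                dimnames = list(NULL, c("Ia", "Ib", "II")))
  for (sc in batches) {
    hit[sc$column, "Ia"] <- hit[sc$column, "Ia"] |
      (!is.na(sc$s_ia) & sc$s_ia > cut["Ia"])
    hit[sc$column, "Ib"] <- hit[sc$column, "Ib"] |
      (!is.na(sc$s_ib) & sc$s_ib > cut["Ib"])
    hit[sc$column, "II"] <- hit[sc$column, "II"] |
      (!is.na(sc$s_ii) & sc$s_ii > cut["II"])
  }
  flagged <- which(rowSums(hit) > 0)
  full <- batches[[1L]]
  methods <- vapply(flagged, function(i)
    paste(c("Ia", "Ib", "II")[hit[i, ]], collapse = ","), character(1))
  n_hit <- length(flagged)
  df <- data.frame(aln_col = as.integer(flagged),
                   gas6_pos1 = rep(NA_integer_, n_hit),
                   gas6_pos2 = rep(NA_integer_, n_hit),
                   gas6_aa = full$modal_1[flagged],
                   pros1_pos = rep(NA_integer_, n_hit),
                   pros1_aa = full$modal_2[flagged],
                   methods = methods, stringsAsFactors = FALSE)
  .validate_site_table(df)
}

#' An external per-site method result (FunDi- or Selectome-style)
#'
#' Houses site lists produced by likelihood mixture-model or branch-site
#' positive-selection methods, ingested from files; only sites whose
#' posterior statistic reaches the method's threshold contribute tags.
#'
#' @param method tag contributed by this method (e.g. `"FD"`, `"PS"`).
#' @param sites data frame with columns `aln_col` and `statistic`
#'   (posterior probability in \[0,1\]).
#' @param threshold retention threshold on `statistic` (default 0.95, the
#'   stringent posterior-probability threshold).
#' @return An `external_result` object.
#' @export
external_result <- function(method, sites, threshold = 0.95) {
  stopifnot(all(c("aln_col", "statistic") %in% names(sites)))
  if (any(sites$statistic < 0 | sites$statistic > 1, na.rm = TRUE))
    stop("posterior statistic must lie in [0, 1]")
  if (!method %in% .SITE_METHODS)
    stop("unknown method tag: ", method)
  structure(list(method = method, sites = sites, threshold = threshold),
            class = "external_result")
}

#' Read an external method result from TSV
#' @param path TSV with header `aln_col<TAB>statistic`.
#' @inheritParams external_result
#' @return An [external_result()].
#' @export
read_external_results <- function(path, method, threshold = 0.95) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  external_result(method, df, threshold)
}

#' Merge internal detections with external method results
#'
#' Sites are unioned by master alignment column; per-site tag sets are
#' unioned. External results contribute their method tag at columns whose
#' statistic is at or above the method threshold. Residue annotations from
#' the internal table are kept; merging two internal tables with
#' conflicting residue annotations at the same column is an error.
#'
#' @param internal a `site_table` (e.g. from [detect_sites()]), indexed by
#'   `aln_col`.
#' @param external list of [external_result()] objects (may be empty).
#' @return A `site_table` ordered by alignment column.
#' @export
merge_method_results <- function(internal, external = list()) {
  if (inherits(external, "external_result")) external <- list(external)
  if (any(is.na(internal$aln_col)))
    stop("internal sites must be indexed by alignment column")
  rows <- as.data.frame(internal, stringsAsFactors = FALSE)
  tags <- stats::setNames(strsplit(rows$methods, ",", fixed = TRUE),
                          rows$aln_col)
  for (ex in external) {
    keep <- ex$sites$aln_col[!is.na(ex$sites$statistic) &
                             ex$sites$statistic >= ex$threshold]
    for (col in keep) {
      key <- as.character(col)
      tags[[key]] <- union(tags[[key]], ex$method)
      if (!col %in% rows$aln_col) {
        rows <- rbind(rows,
                      data.frame(aln_col = as.integer(col),
                                 gas6_pos1 = NA_integer_,
                                 gas6_pos2 = NA_integer_,
                                 gas6_aa = NA_character_,
                                 pros1_pos = NA_integer_,
                                 pros1_aa = NA_character_,
                                 methods = ex$method,
                                 stringsAsFactors = FALSE))
      }
    }
  }
  # residue consistency across duplicate columns (if caller rbinds tables)
  if (anyDuplicated(rows$aln_col)) {
    for (col in unique(rows$aln_col[duplicated(rows$aln_col)])) {
      sub <- rows[rows$aln_col == col, ]
      for (f in c("gas6_aa", "pros1_aa")) {
        v <- unique(sub[[f]][!is.na(sub[[f]])])
        if (length(v) > 1L)
          stop("consistency error: conflicting ", f, " at column ", col)
      }
    }
    rows <- rows[!duplicated(rows$aln_col), , drop = FALSE]
  }
  ord <- .SITE_METHODS
  rows$methods <- vapply(as.character(rows$aln_col), function(k) {
    t <- tags[[k]]
    paste(ord[ord %in% t], collapse = ",")
  }, character(1))
  rows <- rows[order(rows$aln_col), , drop = FALSE]
  rownames(rows) <- NULL
  .validate_site_table(rows)
}
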