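# Stability-divergence statistic: per-clade median ddG per column, the
# absolute between-clade difference, and the divergent vs non-divergent
# group comparison.

.DDG_COLS <- c("position", "wt")

#' Construct / validate a per-position ddG substitution matrix
#'
#' One row per structure position: the wild-type residue and the stability
#' effect \eqn{\Delta\Delta G = \Delta G_{mut} - \Delta G_{wt}} (kcal/mol)
#' of substituting it by each of the 20 amino acids. Positive values are
#' destabilizing. The wt->wt entry is 0 by construction.
#'
#' @param df data frame with columns `position` (integer), `wt` (one-letter
#'   residue) and the 20 amino-acid columns `A` ... `Y`.
#' @return A `ddg_matrix` data frame.
#' @export
ddg_matrix <- function(df) {
  miss <- setdiff(c(.DDG_COLS, AA20), names(df))
  if (length(miss))
    stop("ddG matrix missing column(s): ", paste(miss, collapse = ", "))
  if (any(!df$wt %in% AA20))
    stop("ddG matrix: invalid wild-type residue")
  for (a in AA20) {
    if (!is.numeric(df[[a]]) || any(!is.finite(df[[a]])))
      stop("ddG matrix: non-numeric or non-finite value in column ", a)
  }
  if (anyDuplicated(df$position))
    stop("ddG matrix: duplicate positions")
  df <- df[, c(.DDG_COLS, AA20)]
  class(df) <- c("ddg_matrix", "data.frame")
  df
}

#' Read a ddG substitution matrix from TSV
#'
#' Expected header: `position`, `wt`, then the 20 amino acids. This is the
#' ingestion point for force-field output (e.g. a FoldX position scan) or
#' for [surrogate_ddg()] matrices.
#' @param path TSV path.
#' @return A [ddg_matrix()].
#' @export
read_ddg_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  ddg_matrix(df)
}

#' Write a ddG substitution matrix to TSV
#' @param ddg a [ddg_matrix()].
#' @param path output path.
#' @param header_lines optional `#` provenance lines.
#' @return Invisibly, `path`.
#' @export
write_ddg_matrix <- function(ddg, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(as.data.frame(ddg), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ddG of observing residue `res` at structure position row `i` of `ddg`
.ddg_lookup <- function(ddg, pos_index, residues) {
  vapply(seq_along(residues), function(k) {
    r <- residues[k]
    if (!r %in% AA20) return(NA_real_)
    ddg[[r]][pos_index[k]]
  }, numeric(1))
}

#' Per-clade median ddG at alignment columns
#'
#' For each requested column, every sequence of the clade contributes the
#' stability effect of substituting the structure's wild-type residue by
#' that sequence's residue (single-mutation lookup in the ddG matrix; gaps
#' and `X` are skipped). The clade summary is the median over sequences.
#'
#' @param msa a [clade_msa()].
#' @param clade clade label.
#' @param columns integer vector of alignment columns (default: all).
#' @param ddg a [ddg_matrix()] for the reference structure.
#' @param nmap a [build_numbering_map()] for the sequence the structure
#'   positions refer to.
#' @return Named numeric vector (names = columns) of median ddG in
#'   kcal/mol; `NA` where the column has no structure position or the clade
#'   has no scoreable residue.
#' @export
clade_median_ddg <- function(msa, clade, columns = NULL, ddg, nmap) {
  if (is.null(columns)) columns <- seq_len(msa$n_columns)
  mat <- as.matrix(msa)[clade_ids(msa, clade), , drop = FALSE]
  respos <- nmap$residue[match(columns, nmap$column)]
  pos_index <- match(respos, ddg$position)
  out <- rep(NA_real_, length(columns))
  for (k in seq_along(columns)) {
    if (is.na(pos_index[k])) next
    res <- mat[, columns[k]]
    vals <- .ddg_lookup(ddg, rep(pos_index[k], length(res)), res)
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[k] <- stats::median(vals)
  }
  stats::setNames(out, columns)
}

#' Absolute stability divergence between two clade medians
#'
#' @param med_a,med_b per-column median ddG (kcal/mol); `NA` propagates.
#' @return `|med_a - med_b|`, non-negative and symmetric in its arguments.
#' @export
stability_divergence <- function(med_a, med_b) {
  abs(med_a - med_b)
}

#' Compare stability divergence between divergent and non-divergent sites
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with normal
#' approximation and tie correction, comparing the absolute between-clade
#' stability differences of sites under functional divergence against all
#' other structure-covered sites.
#'
#' @param values numeric vector of per-column `|delta median ddG|`
#'   (kcal/mol), `NA` entries (no structure coverage) dropped.
#' @param divergent logical vector parallel to `values` marking the
#'   divergent group.
#' @return A `stability_comparison`: per-group n, mean and median, the
#'   rank-sum statistic `W` and two-sided `p.value`.
#' @export
compare_site_groups <- function(values, divergent) {
  stopifnot(length(values) == length(divergent))
  keep <- !is.na(values) & !is.na(divergent)
  values <- values[keep]; divergent <- as.logical(divergent[keep])
  x <- values[divergent]; y <- values[!divergent]
  if (!length(x) || !length(y))
    stop("both site groups must be non-empty")
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  structure(list(n_divergent = length(x), n_other = length(y),
                 mean_divergent = mean(x), mean_other = mean(y),
                 median_divergent = stats::median(x),
                 median_other = stats::median(y),
                 statistic = unname(wt$statistic),
                 p.value = wt$p.value),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat("stability_comparison (Wilcoxon rank-sum, two-sided)\n")
  cat(sprintf("  divergent sites:     n=%d  mean=%.3f  median=%.3f kcal/mol\n",
              x$n_divergent, x$mean_divergent, x$median_divergent))
  cat(sprintf("  non-divergent sites: n=%d  mean=%.3f  median=%.3f kcal/mol\n",
              x$n_other, x$mean_other, x$median_other))
  cat(sprintf("  W = %.1f, p = %.4g\n", x$statistic, x$p.value))
  invisible(x)
}

#' Full stability-divergence analysis of an alignment
#'
#' Computes, for every structure-covered alignment column, the per-clade
#' median ddG and the absolute between-clade difference, then compares the
#' divergent against the non-divergent group. Columns without structure
#' coverage are excluded from both groups.
#'
#' @inheritParams clade_median_ddg
#' @param divergent_cols integer vector of alignment columns under
#'   functional divergence.
#' @return list: `per_column` data frame (`column`, `med_1`, `med_2`,
#'   `abs_diff`, `divergent`) restricted to covered columns, and
#'   `comparison`, a `stability_comparison`.
#' @export
stability_analysis <- function(msa, ddg, nmap, divergent_cols) {
  cols <- seq_len(msa$n_columns)
  m1 <- clade_median_ddg(msa, msa$clade_levels[1], cols, ddg, nmap)
  m2 <- clade_median_ddg(msa, msa$clade_levels[2], cols, ddg, nmap)
  d <- stability_divergence(m1, m2)
  covered <- !is.na(d)
  per <- data.frame(column = cols[covered],
                    med_1 = unname(m1[covered]),
                    med_2 = unname(m2[covered]),
                    abs_diff = unname(d[covered]),
                    divergent = cols[covered] %in% divergent_cols)
  list(per_column = per,
       comparison = compare_site_groups(per$abs_diff, per$divergent))
}

#' Classify a stability effect into destabilization bins
#'
#' Bins on \eqn{\Delta\Delta G} (kcal/mol): values at or below 0.5 are
#' neutral, above 0.5 slightly destabilizing, above 1 destabilizing, above
#' 2 strongly destabilizing; values below -0.5 are additionally labelled
#' stabilizing.
#'
#' @param ddg numeric vector of stability effects (kcal/mol, finite).
#' @return character vector of categories.
#' @export
classify_effect <- function(ddg) {
  if (any(!is.finite(ddg))) stop("ddG values must be finite")
  out <- rep("neutral", length(ddg))
  out[ddg > 0.5] <- "slightly destabilizing"
  out[ddg > 1] <- "destabilizing"
  out[ddg > 2] <- "strongly destabilizing"
  out[ddg < -0.5] <- "stabilizing"
  out
}
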