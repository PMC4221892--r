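# Molecular-clock rate calibration from taxon-pair divergence times and
# node dating of (near-)ultrametric trees.

.tip_index <- function(tree, taxon) {
  i <- match(taxon, tree$tip.label)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  i
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths (substitutions/site) on the unique path between
#' two tips.
#' @param tree an [ape::read.tree()] `phylo` with branch lengths.
#' @param taxon_a,taxon_b tip labels.
#' @return Distance in substitutions/site (0 for a taxon against itself).
#' @export
patristic_distance <- function(tree, taxon_a, taxon_b) {
  ia <- .tip_index(tree, taxon_a)
  ib <- .tip_index(tree, taxon_b)
  if (ia == ib) return(0)
  D <- stats::cophenetic(tree)
  D[taxon_a, taxon_b]
}

#' Clock rate implied by one calibrated taxon pair
#'
#' Two lineages diverging `time_ma` million years ago accumulate a
#' patristic distance of twice rate times time, so
#' `r = d / (2 * time_ma)` substitutions/site/Myr.
#'
#' @param d patristic distance (substitutions/site), non-negative.
#' @param time_ma divergence time in Ma, strictly positive.
#' @return Rate in substitutions/site/Myr.
#' @export
pair_rate <- function(d, time_ma) {
  if (any(time_ma <= 0)) stop("divergence time must be > 0")
  if (any(d < 0)) stop("patristic distance must be >= 0")
  d / (2 * time_ma)
}

#' Summarise per-pair clock rates
#'
#' @param rates numeric vector of per-pair rates (at least one).
#' @param method `"median"` (default; an even count averages the middle
#'   two) or `"mean"`.
#' @return Summary rate in substitutions/site/Myr.
#' @export
summary_rate <- function(rates, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!length(rates)) stop("no rates supplied")
  if (method == "median") stats::median(rates) else mean(rates)
}

# distance from the root to every node (tips first, then internals)
.root_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Check approximate ultrametricity
#'
#' A tree is treated as ultrametric when the spread of root-to-tip
#' distances is at most `tol` times the tree height (relaxed-clock
#' consensus trees are near- but rarely exactly ultrametric).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tol relative tolerance on the tip-height spread (default 0.01).
#' @return Invisibly `TRUE`; otherwise an error naming the worst tips.
#' @export
check_ultrametric <- function(tree, tol = 0.01) {
  depths <- .root_depths(tree)[seq_along(tree$tip.label)]
  height <- max(depths)
  spread <- height - min(depths)
  if (height <= 0) stop("tree has zero height")
  if (spread > tol * height) {
    dev <- abs(depths - stats::median(depths))
    worst <- tree$tip.label[order(dev, decreasing = TRUE)]
    worst <- utils::head(worst[dev[order(dev, decreasing = TRUE)] >
                               tol * height / 2], 10L)
    stop("tree is not ultrametric within tolerance (spread ",
         signif(spread, 4), " > ", tol, " x height ", signif(height, 4),
         "); offending tips: ", paste(worst, collapse = ", "))
  }
  invisible(TRUE)
}

#' Node heights of a (near-)ultrametric tree
#'
#' Height of a node = mean root-to-tip distance over its descendant tips
#' minus its own root depth, i.e. the average tip-ward path length in
#' substitutions/site.
#'
#' @inheritParams check_ultrametric
#' @return data frame `node` (ape node ids; tips `1..n`, internals
#'   `n+1..`), `height` (substitutions/site), `is_tip`.
#' @export
node_heights <- function(tree, tol = 0.01) {
  check_ultrametric(tree, tol)
  depths <- .root_depths(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc_sum <- numeric(nnode)
  desc_n <- integer(nnode)
  desc_sum[seq_len(ntip)] <- depths[seq_len(ntip)]
  desc_n[seq_len(ntip)] <- 1L
  # accumulate tip depths bottom-up: edges in postorder visit children first
  eo <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    par <- eo[k, 1L]; chi <- eo[k, 2L]
    desc_sum[par] <- desc_sum[par] + desc_sum[chi]
    desc_n[par] <- desc_n[par] + desc_n[chi]
  }
  height <- desc_sum / desc_n - depths
  data.frame(node = seq_len(nnode), height = height,
             is_tip = seq_len(nnode) <= ntip)
}

#' Convert a node height to an age in Ma
#'
#' Under a strict clock a node `h` substitutions/site above the tips is
#' `h / r` million years old.
#' @param h node height (substitutions/site).
#' @param rate clock rate (substitutions/site/Myr), strictly positive.
#' @return Age in Ma.
#' @export
date_node <- function(h, rate) {
  if (any(rate <= 0)) stop("clock rate must be > 0")
  h / rate
}

#' Date every node of a (near-)ultrametric tree
#'
#' @inheritParams check_ultrametric
#' @param rate clock rate in substitutions/site/Myr.
#' @return data frame from [node_heights()] with an extra `age_ma` column.
#' @export
date_nodes <- function(tree, rate, tol = 0.01) {
  nh <- node_heights(tree, tol)
  nh$age_ma <- date_node(nh$height, rate)
  nh
}

#' Read taxon-pair time calibrations
#' @param path TSV with header `taxon_a<TAB>taxon_b<TAB>time_ma` (times in
#'   Ma, e.g. from a divergence-time database).
#' @return data frame of calibrations.
#' @export
read_calibrations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("taxon_a", "taxon_b", "time_ma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("calibration file missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$time_ma <= 0)) stop("divergence times must be > 0")
  df
}

#' Calibrate a clock rate and date a tree
#'
#' For every calibrated taxon pair the implied rate is the patristic
#' distance over twice the divergence time; the summary rate (median by
#' default) converts node heights to ages when the tree is near-ultrametric.
#'
#' @param tree a rooted `phylo` with branch lengths in substitutions/site.
#' @param calibrations data frame `taxon_a`, `taxon_b`, `time_ma` (Ma).
#' @param method summary method, see [summary_rate()].
#' @param tol ultrametricity tolerance; set `date = FALSE` to skip dating
#'   for non-ultrametric trees.
#' @param date logical; also date all nodes (default `TRUE`).
#' @return A `time_calibrated_tree`: list with the tree, the calibration
#'   table augmented with `distance` and `rate`, the summary `rate`, and
#'   (if dated) the `node_ages` data frame.
#' @export
clock_calibration <- function(tree, calibrations, method = "median",
                              tol = 0.01, date = TRUE) {
  D <- stats::cophenetic(tree)
  d <- mapply(function(a, b) {
    .tip_index(tree, a); .tip_index(tree, b)
    if (a == b) 0 else D[a, b]
  }, calibrations$taxon_a, calibrations$taxon_b)
  calibrations$distance <- unname(d)
  calibrations$rate <- pair_rate(calibrations$distance,
                                 calibrations$time_ma)
  r <- summary_rate(calibrations$rate, method)
  ages <- if (date) date_nodes(tree, r, tol) else NULL
  structure(list(tree = tree, calibrations = calibrations, rate = r,
                 method = method, node_ages = ages),
            class = "time_calibrated_tree")
}

#' @export
print.time_calibrated_tree <- function(x, ...) {
  cat("time_calibrated_tree: ", length(x$tree$tip.label), " tips, ",
      nrow(x$calibrations), " calibrations\n", sep = "")
  cat(sprintf("  %s clock rate: %.6g substitutions/site/Myr\n",
              x$method, x$rate))
  if (!is.null(x$node_ages)) {
    root <- x$node_ages[which.max(x$node_ages$age_ma), ]
    cat(sprintf("  root age: %.1f Ma\n", root$age_ma))
  }
  invisible(x)
}
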