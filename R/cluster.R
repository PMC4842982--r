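# Hierarchical clustering of samples with correlation distance and complete
# linkage, plus approximately-unbiased (AU) cluster support by multiscale
# bootstrap resampling of the probes.
#
# For each resampling scale r, B bootstrap resamples of the probe rows of
# size round(n_probes * r) are reclustered; BP_r is the fraction of
# replicates containing each observed cluster (as a leaf set).  Per cluster,
# psi(r) = qnorm(1 - BP_r) is fitted to v*sqrt(r) + c/sqrt(r) by weighted
# least squares (binomial variance of BP_r propagated through the probit),
# and AU = 1 - pnorm(v - c), BP = 1 - pnorm(v + c).

#' Correlation-distance complete-linkage clustering of samples
#'
#' Pairwise sample distance is `1 - Pearson correlation` of log2 values over
#' the signature probes; agglomeration is complete linkage.  Samples are
#' reordered lexicographically by id first, which makes the result invariant
#' to input order up to that tie-break.
#'
#' @param x expression matrix (SummarizedExperiment/linear matrix) or a log2
#'   matrix when `log = FALSE`.
#' @param probes signature probe ids (default: all probes).
#' @param log apply [log_signal()] first (default TRUE).
#' @return Object of class `cluster_tree`: list with the `hclust` object,
#'   `labels`, `clusters` (list of leaf-label sets per internal node, root
#'   last), `heights`, and (after [au_pvalues()]) the per-edge support table.
#' @export
hcluster <- function(x, probes = NULL, log = TRUE) {
  m <- if (log) log_signal(x) else signal_matrix(x)
  if (!is.null(probes)) {
    miss <- setdiff(probes, rownames(m))
    if (length(miss)) stop("probes absent: ", paste(miss, collapse = ", "))
    m <- m[probes, , drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need >= 2 samples")
  m <- m[, order(colnames(m)), drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s) over the signature: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc, labels = hc$labels,
                 clusters = merge_leaf_sets(hc$merge, hc$labels),
                 heights = hc$height, support = NULL),
            class = "cluster_tree")
}

# Leaf-label sets of the internal nodes of an hclust merge matrix, in merge
# order (root last).
merge_leaf_sets <- function(merge, labels) {
  n <- nrow(merge) + 1L
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    take <- function(j) if (j < 0) labels[-j] else sets[[j]]
    sets[[i]] <- sort(c(take(merge[i, 1L]), take(merge[i, 2L])))
  }
  sets
}

# Bitmask signatures (exact doubles up to 53 leaves) for the internal nodes
# of an hclust on columns ordered as `labels`.
merge_masks <- function(merge, pow2) {
  k <- nrow(merge)
  masks <- numeric(k)
  for (i in seq_len(k)) {
    a <- merge[i, 1L]; b <- merge[i, 2L]
    masks[i] <- (if (a < 0) pow2[-a] else masks[a]) +
                (if (b < 0) pow2[-b] else masks[b])
  }
  masks
}

#' Multiscale-bootstrap AU p-values for a sample dendrogram
#'
#' @param x,probes,log as in [hcluster()].
#' @param scales resampling scales r (must include values below and above 1).
#' @param B bootstrap replicates per scale (>= 100).
#' @param seed integer seed.
#' @return A `cluster_tree` whose `support` element is a data.frame with one
#'   row per internal edge: `au`, `bp` (fitted at r = 1), `bp_raw` (observed
#'   fraction at the scale nearest 1), `v`, `c`, and whose `bp_table`
#'   attribute holds the per-scale BP_r matrix (edges x scales, actual scale
#'   ratios as column names).
#' @export
au_pvalues <- function(x, probes = NULL, scales = seq(0.5, 1.4, by = 0.1),
                       B = 1000L, seed = 1L, log = TRUE) {
  if (!any(scales < 1) || !any(scales > 1))
    stop("scales must span values below and above 1")
  if (B < 100L) stop("B must be >= 100")
  m <- if (log) log_signal(x) else signal_matrix(x)
  if (!is.null(probes)) {
    miss <- setdiff(probes, rownames(m))
    if (length(miss)) stop("probes absent: ", paste(miss, collapse = ", "))
    m <- m[probes, , drop = FALSE]
  }
  tree <- hcluster(m, log = FALSE)
  m <- m[, tree$labels, drop = FALSE]
  np <- nrow(m)
  ns <- ncol(m)
  if (ns > 53L)
    stop("AU bootstrap supports up to 53 samples (bitmask leaf signatures)")
  pow2 <- 2^(seq_len(ns) - 1L)
  obs_masks <- merge_masks(tree$hclust$merge, pow2)
  sizes <- pmax(2L, as.integer(round(np * scales)))
  r_eff <- sizes / np
  counts <- matrix(0L, length(obs_masks), length(scales))
  withr::with_seed(seed, {
    for (s in seq_along(scales)) {
      msz <- sizes[s]
      for (b in seq_len(B)) {
        idx <- sample.int(np, msz, replace = TRUE)
        sub <- m[idx, , drop = FALSE]
        cc <- suppressWarnings(stats::cor(sub))
        cc[!is.finite(cc)] <- 0         # degenerate resample: max distance
        hc <- stats::hclust(stats::as.dist(1 - cc), method = "complete")
        counts[, s] <- counts[, s] +
          (obs_masks %in% merge_masks(hc$merge, pow2))
      }
    }
  })
  bp <- counts / B
  dimnames(bp) <- list(NULL, formatC(r_eff, format = "g"))
  fits <- t(vapply(seq_len(nrow(bp)), function(i)
    fit_au_curve(r_eff, bp[i, ], B), numeric(4)))
  support <- data.frame(
    edge = seq_len(nrow(bp)),
    au = fits[, 1], bp = fits[, 2],
    bp_raw = bp[, which.min(abs(r_eff - 1))],
    v = fits[, 3], c = fits[, 4],
    row.names = NULL)
  if (any(rowSums(counts) == 0))
    warning("cluster(s) never observed in any replicate; AU set to 0: edges ",
            paste(which(rowSums(counts) == 0), collapse = ", "))
  tree$support <- support
  attr(tree$support, "bp_table") <- bp
  attr(tree$support, "B") <- B
  attr(tree$support, "scales") <- r_eff
  tree
}

#' Fit the multiscale-bootstrap model to per-scale bootstrap probabilities
#'
#' Fits `qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r)` by least squares weighted
#' by the (delta-method) binomial variance of the probit-transformed BP_r,
#' after clipping BP_r to `[1/(B+1), B/(B+1)]`.  Degenerate cases: all BP_r
#' at the upper clip give AU = BP = 1; all at the lower clip give AU = BP = 0.
#'
#' @param r numeric vector of (actual) resampling scales.
#' @param bp bootstrap probabilities per scale.
#' @param B replicates per scale.
#' @return Numeric vector `c(au, bp, v, c)`.
#' @export
fit_au_curve <- function(r, bp, B) {
  if (all(bp >= 1)) return(c(au = 1, bp = 1, v = NA_real_, c = NA_real_))
  if (all(bp <= 0)) return(c(au = 0, bp = 0, v = NA_real_, c = NA_real_))
  bpc <- pmin(pmax(bp, 1 / (B + 1)), B / (B + 1))
  psi <- stats::qnorm(1 - bpc)
  w <- stats::dnorm(psi)^2 * B / (bpc * (1 - bpc))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% psi)
  v <- beta[1L]; cc <- beta[2L]
  c(au = 1 - stats::pnorm(v - cc), bp = 1 - stats::pnorm(v + cc),
    v = v, c = cc)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(x$labels), "samples,",
      length(x$clusters), "internal nodes\n")
  if (!is.null(x$support)) {
    strong <- sum(x$support$au > 0.95)
    cat("  AU support available;", strong, "edge(s) with AU > 0.95\n")
  }
  invisible(x)
}

#' Write a cluster tree as annotated Newick
#'
#' Internal nodes carry `[AU=..,BP=..]` comment annotations after their
#' closing parenthesis when support is available.
#'
#' @param tree a `cluster_tree`.
#' @param path output file; `NULL` returns the string.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_cluster_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  sup <- tree$support
  # ultrametric: a child's branch length is parent height minus child height
  node_str <- function(i, parent_h) {
    if (i < 0)
      return(sprintf("%s:%g", hc$labels[-i], parent_h))
    h <- hc$height[i]
    s <- sprintf("(%s,%s)", node_str(hc$merge[i, 1L], h),
                 node_str(hc$merge[i, 2L], h))
    ann <- if (!is.null(sup))
      sprintf("[AU=%.3f,BP=%.3f]", sup$au[i], sup$bp[i]) else ""
    sprintf("%s%s:%g", s, ann, max(parent_h - h, 0))
  }
  k <- nrow(hc$merge)
  hroot <- hc$height[k]
  root <- sprintf("(%s,%s)%s;",
                  node_str(hc$merge[k, 1L], hroot),
                  node_str(hc$merge[k, 2L], hroot),
                  if (!is.null(sup))
                    sprintf("[AU=%.3f,BP=%.3f]", sup$au[k], sup$bp[k])
                  else "")
  if (is.null(path)) return(root)
  writeLines(root, path)
  invisible(root)
}
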