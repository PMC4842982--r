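# PCA of progenitor cells and constrained rotation of the leading two
# components into a differentiation axis (NewX) and a temporal axis (NewY):
#   NewX =  cos(theta) * PC1 + sin(theta) * PC2
#   NewY = -sin(theta) * PC1 + cos(theta) * PC2
# with theta chosen so the median NewX of the anchor cell group is equal at
# two stages (the anchor population's temporal separation is pushed onto
# NewY, leaving NewX to encode differentiation).

#' PCA of cells on log2 signals
#'
#' Mean-centered, unscaled PCA (no per-gene standardization) of cells over
#' probes.  Component signs are fixed: with `stages` supplied, each
#' component is flipped so the latest stage has the higher median score;
#' otherwise the largest-magnitude loading of each component is made
#' positive.
#'
#' @param x expression matrix (SummarizedExperiment/linear matrix) or log2
#'   matrix when `log = FALSE`.
#' @param stages optional stage label per cell (for the sign convention);
#'   taken from `colData(x)$stage` when `x` is a SummarizedExperiment.
#' @param log apply [log_signal()] first (default TRUE).
#' @return Object of class `pca_model`: `center` (per-gene means), `loadings`
#'   (genes x components, orthonormal), `scores` (cells x components),
#'   `var_frac` (non-increasing variance fractions), `stages`.
#' @export
fit_pca <- function(x, stages = NULL, log = TRUE) {
  if (is.null(stages) && methods::is(x, "SummarizedExperiment"))
    stages <- stage_labels(x)
  m <- if (log) log_signal(x) else signal_matrix(x)
  if (ncol(m) < 3L) stop("need >= 3 cells for PCA")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  flip <- rep(1, ncol(pc$rotation))
  if (!is.null(stages)) {
    stages <- as.character(stages)
    lev <- order_stages(stages)
    first <- stages == lev[1L]
    last <- stages == lev[length(lev)]
    for (j in seq_along(flip)) {
      d <- median(pc$x[last, j]) - median(pc$x[first, j])
      if (d < 0) flip[j] <- -1
    }
  } else {
    for (j in seq_along(flip))
      if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0)
        flip[j] <- -1
  }
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  structure(list(center = pc$center, loadings = loadings, scores = scores,
                 var_frac = pc$sdev^2 / sum(pc$sdev^2), stages = stages),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", nrow(x$scores), "cells,", nrow(x$loadings), "genes\n",
      " variance fractions:",
      paste(formatC(head(x$var_frac, 4), digits = 3), collapse = " "), "\n")
  invisible(x)
}

# Median NewX difference between the two anchor groups at angle theta (rad).
rotation_constraint <- function(theta, a1, a2, b1, b2) {
  ct <- cos(theta); st <- sin(theta)
  fast_median(ct * b1 + st * b2) - fast_median(ct * a1 + st * a2)
}

#' Solve the median-equality rotation angle
#'
#' Finds theta in \[-90, 90) degrees with
#' `median(NewX | anchor stage B) == median(NewX | anchor stage A)`
#' by a sign-change scan on a 0.01-degree grid followed by bisection to a
#' residual below `tol` (relative to the score scale).  When several roots
#' exist, the root maximizing the anchor groups' NewY median separation is
#' returned (the constraint is meant to push temporal separation onto NewY);
#' all roots are reported.
#'
#' @param scores cells x >= 2 matrix of PC scores, or a `pca_model`.
#' @param anchor_a,anchor_b row indices (or cell-id character vectors) of the
#'   anchor cells at the earlier/later stage.
#' @param grid_deg scan step in degrees (default 0.01).
#' @param tol relative residual tolerance (default 1e-9).
#' @return Object of class `rotation_result`: `theta_rad`, `theta_deg`,
#'   `sin`, `cos`, `residual`, `roots_deg` (all roots), `newy_sep`.
#' @export
solve_rotation <- function(scores, anchor_a, anchor_b,
                           grid_deg = 0.01, tol = 1e-9) {
  if (inherits(scores, "pca_model")) scores <- scores$scores
  sc <- as.matrix(scores)[, 1:2, drop = FALSE]
  ai <- resolve_cells(anchor_a, rownames(sc))
  bi <- resolve_cells(anchor_b, rownames(sc))
  if (length(ai) == 0L || length(bi) == 0L)
    stop("both anchor groups must be non-empty")
  a1 <- sc[ai, 1L]; a2 <- sc[ai, 2L]
  b1 <- sc[bi, 1L]; b2 <- sc[bi, 2L]
  scale <- max(abs(sc))
  if (scale == 0) scale <- 1
  tol_abs <- tol * scale

  grid <- seq(-90, 90, by = grid_deg) * pi / 180
  fg <- vapply(grid, rotation_constraint, 0, a1 = a1, a2 = a2,
               b1 = b1, b2 = b2)
  roots <- grid[fg == 0]
  sign_change <- which(fg[-length(fg)] * fg[-1L] < 0)
  for (i in sign_change) {
    lo <- grid[i]; hi <- grid[i + 1L]
    flo <- fg[i]
    # medians are piecewise linear in theta, so bisection to interval width
    # ~1e-14 rad drives the residual far below tol on any sane score scale
    for (it in seq_len(200L)) {
      mid <- (lo + hi) / 2
      fm <- rotation_constraint(mid, a1, a2, b1, b2)
      if (fm == 0 || (hi - lo) < 1e-14) break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    if (abs(fm) > tol_abs)
      warning("rotation residual ", fm, " above tolerance")
    roots <- c(roots, mid)
  }
  roots <- roots[!duplicated(round(roots, 12))]
  if (length(roots) == 0L)
    stop(sprintf(
      "constraint unsatisfiable: no sign change of the median difference over [-90, 90); f range [%g, %g]",
      min(fg), max(fg)))
  newy_sep <- vapply(roots, function(th) {
    ct <- cos(th); st <- sin(th)
    abs(fast_median(-st * b1 + ct * b2) - fast_median(-st * a1 + ct * a2))
  }, 0)
  best <- which.max(newy_sep)
  theta <- roots[best]
  # map into [-90, 90)
  theta_deg <- theta * 180 / pi
  if (theta_deg >= 90) theta_deg <- theta_deg - 180
  theta <- theta_deg * pi / 180
  structure(list(theta_rad = theta, theta_deg = theta_deg,
                 sin = sin(theta), cos = cos(theta),
                 residual = rotation_constraint(theta, a1, a2, b1, b2),
                 roots_deg = roots * 180 / pi,
                 newy_sep = newy_sep[best]),
            class = "rotation_result")
}

resolve_cells <- function(sel, ids) {
  if (is.character(sel)) {
    idx <- match(sel, ids)
    if (anyNA(idx)) stop("unknown cell ids: ",
                         paste(sel[is.na(idx)], collapse = ", "))
    idx
  } else {
    seq_along(ids)[sel]
  }
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf(
    "rotation_result: theta = %.4f deg (sin = %.7f, cos = %.7f)\n  residual = %g; %d root(s) found\n",
    x$theta_deg, x$sin, x$cos, x$residual, length(x$roots_deg)))
  invisible(x)
}

#' Rotate PCA scores and loadings into the new axes
#'
#' Applies the orthonormal 2x2 rotation to the leading two components of
#' scores and loadings; higher components pass through unrotated.
#'
#' @param pca a `pca_model`.
#' @param rot a `rotation_result` derived from this model's leading two
#'   components.
#' @return list with `scores` (cells x components; first two columns `NewX`,
#'   `NewY`), `loadings` (genes x components, same renaming), `rotation`.
#' @export
rotate_axes <- function(pca, rot) {
  stopifnot(inherits(pca, "pca_model"), inherits(rot, "rotation_result"))
  R <- rbind(c(rot$cos, rot$sin), c(-rot$sin, rot$cos))
  sc <- pca$scores
  ld <- pca$loadings
  sc[, 1:2] <- sc[, 1:2, drop = FALSE] %*% t(R)
  ld[, 1:2] <- ld[, 1:2, drop = FALSE] %*% t(R)
  colnames(sc)[1:2] <- colnames(ld)[1:2] <- c("NewX", "NewY")
  list(scores = sc, loadings = ld, rotation = rot)
}

#' Extract temporal- and differentiation-axis genes from rotated loadings
#'
#' Temporal lists are the top-k most positive and most negative NewY
#' loadings; differentiation lists likewise on NewX.  Ties break by gene id.
#'
#' @param loadings rotated loading matrix (genes x components, columns
#'   `NewX`, `NewY`), e.g. `rotate_axes(...)$loadings`.
#' @param k genes per sign (default 10).
#' @return Object of class `axis_gene_set`: `temporal_pos`, `temporal_neg`,
#'   `differentiation_pos`, `differentiation_neg`, `table` (full ranking).
#' @export
axis_genes <- function(loadings, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(loadings)) stop("k exceeds the number of genes")
  ids <- rownames(loadings)
  if (is.null(ids)) stop("loadings must have gene row names")
  topk <- function(v, decreasing) {
    o <- if (decreasing) order(-v, ids) else order(v, ids)  # ties by gene id
    ids[o][seq_len(k)]
  }
  tab <- data.frame(gene_id = ids,
                    newx = loadings[, "NewX"], newy = loadings[, "NewY"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    temporal_pos = topk(tab$newy, TRUE),
    temporal_neg = topk(tab$newy, FALSE),
    differentiation_pos = topk(tab$newx, TRUE),
    differentiation_neg = topk(tab$newx, FALSE),
    table = tab[order(-abs(tab$newy)), ]),
    class = "axis_gene_set")
}

#' @export
print.axis_gene_set <- function(x, ...) {
  cat("axis_gene_set (k =", length(x$temporal_pos), "per sign)\n",
      " temporal +:", paste(x$temporal_pos, collapse = " "), "\n",
      " temporal -:", paste(x$temporal_neg, collapse = " "), "\n")
  invisible(x)
}

#' Parallelism of temporal shifts between two cell classes
#'
#' Fraction of temporal genes whose mean log2 shift between two stages has
#' the same sign in both cell classes, with a permutation p-value obtained by
#' shuffling class labels within stage.
#'
#' @param x expression matrix or log2 matrix (`log = FALSE`).
#' @param temporal_genes gene ids to evaluate.
#' @param classes,stages per-cell class and stage labels.
#' @param class_a,class_b the two classes (default `"AP"`, `"IP"`).
#' @param stage_a,stage_b the two stages.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param log apply [log_signal()] first (default TRUE).
#' @return list: `agreement`, `p_value`, `shifts` (per-gene shift matrix).
#' @export
parallel_shift_stat <- function(x, temporal_genes, classes, stages,
                                class_a = "AP", class_b = "IP",
                                stage_a, stage_b, n_perm = 1000L, seed = 1L,
                                log = TRUE) {
  m <- if (log) log_signal(x) else signal_matrix(x)
  miss <- setdiff(temporal_genes, rownames(m))
  if (length(miss)) stop("genes absent: ", paste(miss, collapse = ", "))
  m <- m[temporal_genes, , drop = FALSE]
  keep <- stages %in% c(stage_a, stage_b) & classes %in% c(class_a, class_b)
  m <- m[, keep, drop = FALSE]
  cl <- classes[keep]; st <- stages[keep]
  for (s in c(stage_a, stage_b)) for (cc in c(class_a, class_b))
    if (!any(st == s & cl == cc))
      stop("class ", cc, " missing at stage ", s)
  agree_fun <- function(cl) {
    sh_a <- rowMeans(m[, cl == class_a & st == stage_b, drop = FALSE]) -
      rowMeans(m[, cl == class_a & st == stage_a, drop = FALSE])
    sh_b <- rowMeans(m[, cl == class_b & st == stage_b, drop = FALSE]) -
      rowMeans(m[, cl == class_b & st == stage_a, drop = FALSE])
    list(agree = mean(sign(sh_a) == sign(sh_b)), shifts = cbind(sh_a, sh_b))
  }
  obs <- agree_fun(cl)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    clp <- cl
    for (s in unique(st)) {
      j <- which(st == s)
      clp[j] <- cl[sample(j)]
    }
    agree_fun(clp)$agree
  }, 0))
  list(agreement = obs$agree,
       p_value = (1 + sum(perm >= obs$agree)) / (n_perm + 1),
       shifts = obs$shifts)
}
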