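# qPCR panel normalization, reference temporal component on wild-type cells,
# projection of perturbed cells, and the nonparametric group comparisons.

#' Normalize a qPCR Ct table against a reference gene
#'
#' Returns `40 - (Ct_gene - Ct_reference)` per gene and cell (the `[40 - Ct]`
#' convention after reference normalization).  Cells in which the reference
#' is undetected are excluded with a warning.  Undetected genes (Ct = 40)
#' are censored: floored to the minimum detected normalized value over the
#' cell set minus 1 (recorded in the `censored` attribute).
#'
#' @param q a [qpcr_table()].
#' @param reference reference gene id (default `"Gapdh"`).
#' @return Numeric matrix (genes x cells, reference row dropped) with
#'   attributes `censored` (logical matrix), `excluded_cells`, `reference`,
#'   `floor`.
#' @export
qpcr_normalize <- function(q, reference = "Gapdh") {
  stopifnot(inherits(q, "qpcr_table"))
  if (!reference %in% rownames(q$ct))
    stop("reference gene '", reference, "' not in table")
  ref_det <- q$detected[reference, ]
  excluded <- colnames(q$ct)[!ref_det]
  if (length(excluded))
    warning("reference '", reference, "' undetected; excluding cell(s): ",
            paste(excluded, collapse = ", "))
  ct <- q$ct[setdiff(rownames(q$ct), reference), ref_det, drop = FALSE]
  det <- q$detected[rownames(ct), ref_det, drop = FALSE]
  nm <- 40 - sweep(ct, 2L, q$ct[reference, ref_det], "-")
  if (!any(det)) stop("no detected values to normalize")
  floor_val <- min(nm[det]) - 1
  nm[!det] <- floor_val
  attr(nm, "censored") <- !det
  attr(nm, "excluded_cells") <- excluded
  attr(nm, "reference") <- reference
  attr(nm, "floor") <- floor_val
  nm
}

#' Fit the reference temporal component on wild-type cells
#'
#' Mean-centered, unscaled PCA of the training cells restricted to the gene
#' panel; Component 1 is stored with its sign oriented so the latest training
#' stage has the highest median score.
#'
#' @param nm normalized matrix from [qpcr_normalize()] (genes x cells).
#' @param stages stage label per training cell.
#' @param panel gene panel (default: all rows of `nm`), fixed at fit time.
#' @return Object of class `reference_axis`: `panel`, `center`, `loading`
#'   (unit norm), `scores` (training cells), `stages`, `var_frac`.
#' @export
fit_reference_axis <- function(nm, stages, panel = rownames(nm)) {
  miss <- setdiff(panel, rownames(nm))
  if (length(miss)) stop("panel gene(s) missing from matrix: ",
                         paste(miss, collapse = ", "))
  if (ncol(nm) < 3L) stop("need >= 3 training cells")
  stages <- as.character(stages)
  if (length(stages) != ncol(nm))
    stop("length(stages) must equal the number of cells")
  if (length(unique(stages)) < 2L) stop("training cells must span >= 2 stages")
  m <- nm[panel, , drop = FALSE]
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  loading <- pc$rotation[, 1L]
  scores <- pc$x[, 1L]
  lev <- order_stages(stages)
  d <- median(scores[stages == lev[length(lev)]]) -
    median(scores[stages == lev[1L]])
  if (d < 0) { loading <- -loading; scores <- -scores }
  structure(list(panel = panel, center = pc$center, loading = loading,
                 scores = scores, stages = stages,
                 var_frac = pc$sdev[1L]^2 / sum(pc$sdev^2)),
            class = "reference_axis")
}

#' @export
print.reference_axis <- function(x, ...) {
  cat("reference_axis:", length(x$panel), "genes,", length(x$scores),
      "training cells; Component 1 carries",
      sprintf("%.1f%%", 100 * x$var_frac), "of variance\n")
  invisible(x)
}

#' Project cells onto a fitted reference component
#'
#' `score = (value - training center) . Component-1 loading`.  Projecting a
#' training cell reproduces its fitted score exactly.
#'
#' @param axis a `reference_axis`.
#' @param nm normalized matrix (genes x cells) containing the full panel.
#' @return Named numeric vector of per-cell scores.
#' @export
project_cells <- function(axis, nm) {
  stopifnot(inherits(axis, "reference_axis"))
  miss <- setdiff(axis$panel, rownames(nm))
  if (length(miss)) stop("panel gene(s) missing from matrix: ",
                         paste(miss, collapse = ", "))
  m <- nm[axis$panel, , drop = FALSE]
  drop(crossprod(m - axis$center, axis$loading))[colnames(m)]
}

#' Two-tailed Mann-Whitney U comparison of score vectors
#'
#' Exact p by enumeration of the U null distribution when
#' `n_a * n_b <= max_exact` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b numeric score vectors.
#' @param max_exact product-size limit for the exact path (default 400).
#' @return list: `U` (statistic for `a`), `p`, `method` (`"exact"` or
#'   `"normal-approx"`).
#' @export
compare_scores <- function(a, b, max_exact = 400) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (na * nb <= max_exact && !has_ties) {
    p_le <- stats::pwilcox(u, na, nb)
    p_ge <- stats::pwilcox(na * nb - u, na, nb)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = u, p = p, method = "exact"))
  }
  n <- na + nb
  mu <- na * nb / 2
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_corr)
  if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal-approx"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal-approx")
}

#' Two-sided Fisher's exact test on detection frequencies
#'
#' Compares the detection frequency of a gene between two cell groups:
#' exact hypergeometric two-sided p (sum of table probabilities not exceeding
#' the observed one).
#'
#' @param flags_a,flags_b logical detection flags per cell in each group.
#' @return list: `p`, `table` (2x2: group x detected/undetected).
#' @export
detection_freq_test <- function(flags_a, flags_b) {
  if (length(flags_a) == 0L || length(flags_b) == 0L)
    stop("both groups must be non-empty")
  x <- sum(flags_a); m_ <- length(flags_a)
  y <- sum(flags_b); n_ <- length(flags_b)
  k <- x + y
  support <- max(0, k - n_):min(m_, k)
  probs <- stats::dhyper(support, m_, n_, k)
  p_obs <- stats::dhyper(x, m_, n_, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tab <- matrix(c(x, m_ - x, y, n_ - y), 2L, byrow = TRUE,
                dimnames = list(c("group_a", "group_b"),
                                c("detected", "undetected")))
  list(p = min(1, p), table = tab)
}

#' Per-stage dispersion of scores
#'
#' @param scores numeric score vector.
#' @param stages stage label per score.
#' @return data.frame (stage, n, iqr, variance, widest) in developmental
#'   order; `widest` flags the stage with the maximal IQR.
#' @export
stage_dispersion <- function(scores, stages) {
  stages <- as.character(stages)
  if (length(scores) != length(stages))
    stop("scores and stages must have equal length")
  lev <- order_stages(stages)
  out <- do.call(rbind, lapply(lev, function(s) {
    v <- scores[stages == s]
    data.frame(stage = s, n = length(v), iqr = stats::IQR(v),
               variance = if (length(v) > 1) stats::var(v) else 0,
               stringsAsFactors = FALSE)
  }))
  out$widest <- seq_len(nrow(out)) == which.max(out$iqr)
  rownames(out) <- NULL
  out
}
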