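# Marker-gate cell classification and signature (ANOVA/FDR) selection.

#' Marker gating rule set
#'
#' Ordered rules; the first rule whose required-positive genes are all
#' detected and required-negative genes all undetected assigns its class.
#'
#' @param ... named lists, each with elements `positive` and `negative`
#'   (character vectors of gene ids); names are the class labels.
#' @return Object of class `marker_rules`.
#' @examples
#' marker_rules(AP = list(positive = c("Mki67", "Ttyh1"),
#'                        negative = "Eomes"))
#' @export
marker_rules <- function(...) {
  rules <- list(...)
  if (length(rules) == 0L || is.null(names(rules)) ||
      any(!nzchar(names(rules))))
    stop("rules must be named (class labels)")
  for (nm in names(rules)) {
    r <- rules[[nm]]
    pos <- r$positive %||% character(0)
    neg <- r$negative %||% character(0)
    both <- intersect(pos, neg)
    if (length(both))
      stop("rule '", nm, "': gene(s) both positive and negative: ",
           paste(both, collapse = ", "))
    rules[[nm]] <- list(positive = pos, negative = neg)
  }
  structure(rules, class = "marker_rules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default progenitor gating rules
#'
#' Wild-type apical progenitors are gated as Ki67+/Ttyh1+/Tbr2(Eomes)-;
#' with `arrest = TRUE`, arrested APs are gated as Egfp+/Ttyh1+/Tbr2- with
#' Ki67 required absent (cell-cycle arrest), followed by a transgenic
#' cycling-AP rule.
#'
#' @param arrest logical; gate transgenic/arrested cells instead of wild type.
#' @return A [marker_rules()] object.
#' @export
progenitor_rules <- function(arrest = FALSE) {
  if (arrest) {
    marker_rules(
      `arrested-AP` = list(positive = c("Egfp", "Ttyh1"),
                           negative = c("Eomes", "Mki67")),
      `transgenic-AP` = list(positive = c("Egfp", "Ttyh1", "Mki67"),
                             negative = "Eomes"))
  } else {
    marker_rules(
      AP = list(positive = c("Mki67", "Ttyh1"), negative = "Eomes"),
      IP = list(positive = c("Mki67", "Eomes"), negative = character(0)))
  }
}

#' Classify cells by marker gating
#'
#' Positivity is the platform detection call: Ct < 40 for qPCR tables,
#' signal >= `threshold` for arrays.  Rules are applied in order; unmatched
#' cells are labelled `"unclassified"`.
#'
#' @param x [qpcr_table()] or expression matrix.
#' @param rules a [marker_rules()] object.
#' @param threshold detection threshold (required for array input; see
#'   [copy_threshold()]).
#' @return Named character vector of class labels per cell.
#' @export
marker_gate <- function(x, rules, threshold = NULL) {
  stopifnot(inherits(rules, "marker_rules"))
  if (inherits(x, "qpcr_table")) {
    det <- x$detected
  } else {
    m <- signal_matrix(x)
    if (is.null(threshold)) stop("threshold is required for array input")
    det <- m >= threshold
  }
  for (nm in names(rules)) {
    genes <- c(rules[[nm]]$positive, rules[[nm]]$negative)
    miss <- setdiff(genes, rownames(det))
    if (length(miss))
      stop("rule '", nm, "' references unmeasured gene(s): ",
           paste(miss, collapse = ", "))
  }
  labels <- rep("unclassified", ncol(det))
  names(labels) <- colnames(det)
  open <- rep(TRUE, ncol(det))
  for (nm in names(rules)) {
    r <- rules[[nm]]
    ok <- open
    if (length(r$positive))
      ok <- ok & colSums(!det[r$positive, , drop = FALSE]) == 0L
    if (length(r$negative))
      ok <- ok & colSums(det[r$negative, , drop = FALSE]) == 0L
    labels[ok] <- nm
    open <- open & !ok
  }
  labels
}

# Vectorized one-way fixed-effects ANOVA over the rows of a matrix.
# Returns F, p, and within/between sums of squares.  Rows with zero
# within-group variance get p = 0 if group means differ, p = 1 if constant.
anova_rows <- function(m, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(m)
  if (k < 2L) stop("need >= 2 groups")
  cnt <- as.vector(table(groups))
  if (any(cnt < 2L)) stop("every group needs >= 2 cells")
  G <- stats::model.matrix(~ 0 + groups)           # n x k indicator
  sums <- m %*% G                                   # row sums per group
  means <- sweep(sums, 2L, cnt, "/")
  grand <- rowSums(m) / n
  ssb <- rowSums(sweep((means - grand)^2, 2L, cnt, "*"))
  sst <- rowSums(m^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  eps <- 1e-12 * pmax(rowMeans(m^2), 1)
  degen <- ssw <= eps
  p[degen & ssb > eps] <- 0
  p[degen & ssb <= eps] <- 1
  f[degen] <- NA_real_
  list(f = f, p = p, means = means, counts = cnt,
       levels = levels(groups))
}

#' Select a signature probe set by one-way ANOVA and FDR
#'
#' Per-probe one-way ANOVA of log2 values across cell groups; q-values from
#' the p-value vector; probes with q below the FDR cut are the signature.
#'
#' @param x expression matrix (SummarizedExperiment or linear-scale matrix) or
#'   a log2 matrix when `log = FALSE`.
#' @param groups group label per cell (>= 2 groups, each >= 2 cells).
#' @param fdr FDR threshold (default 0.1).
#' @param method q-value method, see [qvalues()] (default auto: Storey with
#'   BH fallback for small probe sets).
#' @param log apply [log_signal()] first (default TRUE).
#' @return Character vector of signature probe ids, with the full per-probe
#'   statistics table as attribute `"table"`.
#' @export
signature_select <- function(x, groups, fdr = 0.1, method = NULL,
                             log = TRUE) {
  m <- if (log) log_signal(x) else signal_matrix(x)
  if (length(groups) != ncol(m))
    stop("length(groups) must equal the number of cells")
  a <- anova_rows(m, groups)
  q <- if (is.null(method)) qvalues(a$p) else qvalues(a$p, method = method)
  tab <- data.frame(probe_id = rownames(m), F = a$f, p = a$p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  sig <- tab$probe_id[tab$q < fdr]
  attr(sig, "table") <- tab
  sig
}
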