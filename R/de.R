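# Stage-wise differential-expression selection: per-probe one-way ANOVA on
# log2 values, q-values (Storey or Benjamini-Hochberg), and pairwise log
# fold-change thresholds.

#' q-values from a p-value vector
#'
#' `method = "storey"` estimates pi0 by the smoother over
#' lambda in 0.05, 0.10, ..., 0.95 (natural cubic smoothing spline, df = 3,
#' evaluated at the largest lambda) and sets
#' `q_i = min_{j: p_j >= p_i} pi0 * p_j * m / rank(p_j)`;
#' `method = "bh"` is the same with pi0 = 1.  When the Storey estimate is
#' unusable (non-finite or <= 0, as happens for tiny vectors), the function
#' falls back to BH with a warning.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"storey"` (default) or `"bh"`.
#' @return q-value vector, same order as `p`.
#' @export
qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- 1
  if (method == "storey" && m < 100L) {
    warning("fewer than 100 p-values; Storey pi0 unstable, ",
            "falling back to BH (pi0 = 1)")
    method <- "bh"
  }
  if (method == "storey") {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    pi0 <- tryCatch({
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }, error = function(e) NA_real_)
    if (!is.finite(pi0) || pi0 <= 0) {
      warning("Storey pi0 estimate unstable; falling back to BH (pi0 = 1)")
      pi0 <- 1
    }
    pi0 <- min(pi0, 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  rank_desc <- m:1L                       # rank of the ordered (desc) p's
  q <- cummin(pi0 * p[o] * m / rank_desc)
  pmin(q[ro], 1)
}

#' Stage-wise differential expression selection
#'
#' One-way fixed-effects ANOVA per probe on log2 values across stages,
#' q-values on the p-value vector, and per-contrast log fold changes
#' (difference of stage means of log2 values).  A probe passes when
#' `q < fdr` and its largest absolute contrast logFC exceeds `lfc`.
#'
#' @param x expression matrix (SummarizedExperiment/linear matrix), typically
#'   restricted to the detected (Over-N) probe set, or a log2 matrix when
#'   `log = FALSE`.
#' @param stages stage label per cell (>= 2 stages, >= 2 cells each).
#' @param contrasts list of length-2 character vectors `c(stageA, stageB)`;
#'   default: consecutive stage pairs in developmental order.
#' @param fdr FDR threshold (default 0.1).
#' @param lfc absolute log2 fold-change threshold (default 2.5).
#' @param method q-value method (default auto: Storey, BH fallback when the
#'   probe set is small, < 100 probes).
#' @param log apply [log_signal()] first (default TRUE).
#' @return A `de_table` data.frame: probe_id, F, p, q, one `logFC_<A>_vs_<B>`
#'   column per contrast, pass.  Attributes: `fdr`, `lfc`, `log_base` (2),
#'   `pi0_method`, and `contrast_counts` (among passing probes, how many
#'   exceed `lfc` in each contrast).
#' @export
stagewise_de <- function(x, stages, contrasts = NULL, fdr = 0.1, lfc = 2.5,
                         method = NULL, log = TRUE) {
  m <- if (log) log_signal(x) else signal_matrix(x)
  stages <- as.character(stages)
  if (length(stages) != ncol(m))
    stop("length(stages) must equal the number of cells")
  lev <- order_stages(stages)
  if (length(lev) < 2L) stop("need >= 2 stages")
  if (is.null(contrasts))
    contrasts <- lapply(seq_len(length(lev) - 1L),
                        function(i) c(lev[i], lev[i + 1L]))
  for (ct in contrasts) {
    bad <- setdiff(ct, lev)
    if (length(bad))
      stop("contrast names absent stage(s): ", paste(bad, collapse = ", "))
  }
  a <- anova_rows(m, factor(stages, levels = lev))
  if (is.null(method))
    method <- if (nrow(m) < 100L) "bh" else "storey"
  q <- qvalues(a$p, method = method)
  tab <- data.frame(probe_id = rownames(m), F = a$f, p = a$p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  lfc_mat <- vapply(contrasts, function(ct) {
    a$means[, match(ct[2], a$levels)] - a$means[, match(ct[1], a$levels)]
  }, numeric(nrow(m)))
  cn <- vapply(contrasts, function(ct)
    sprintf("logFC_%s_vs_%s", ct[1], ct[2]), "")
  colnames(lfc_mat) <- cn
  tab <- cbind(tab, as.data.frame(lfc_mat))
  max_lfc <- apply(abs(lfc_mat), 1L, max)
  tab$pass <- tab$q < fdr & max_lfc > lfc
  attr(tab, "fdr") <- fdr
  attr(tab, "lfc") <- lfc
  attr(tab, "log_base") <- 2
  attr(tab, "pi0_method") <- method
  cc <- colSums(abs(lfc_mat[tab$pass, , drop = FALSE]) > lfc)
  mode(cc) <- "integer"
  attr(tab, "contrast_counts") <- cc
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' @export
print.de_table <- function(x, ...) {
  cat("de_table:", nrow(x), "probes;", sum(x$pass), "pass (FDR <",
      attr(x, "fdr"), ", |logFC| >", attr(x, "lfc"), ")\n")
  cc <- attr(x, "contrast_counts")
  if (length(cc))
    cat("  passing probes above |logFC| threshold per contrast:",
        paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
  invisible(x)
}
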