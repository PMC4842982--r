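# Internal helpers shared across modules.

# Median via partial sort; noticeably faster than stats::median inside the
# rotation grid search where it is called tens of thousands of times.
fast_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  half <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort(x, partial = half)[half]
  } else {
    xs <- sort(x, partial = c(half, half + 1L))
    (xs[half] + xs[half + 1L]) / 2
  }
}

# Extract a probes x cells numeric matrix of linear-scale signals from a
# SummarizedExperiment or a plain matrix.
signal_matrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, "signal")
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop("expected a SummarizedExperiment or a matrix, got ", class(x)[1])
  }
  if (is.null(rownames(m))) stop("signal matrix must have probe row names")
  if (is.null(colnames(m))) stop("signal matrix must have cell column names")
  m
}

#' Log-transform linear-scale signals
#'
#' The package performs all statistics on `log2(signal + 1)`.  The +1 offset
#' keeps dropout zeros finite; for detected signals (hundreds of units and
#' above) it is negligible.
#'
#' @param x `SummarizedExperiment` with a `signal` assay, or a numeric matrix
#'   of linear-scale signals.
#' @return Numeric matrix of log2 values, probes x cells.
#' @export
log_signal <- function(x) {
  m <- signal_matrix(x)
  if (any(m < 0)) stop("negative signal values: corrupt input")
  log2(m + 1)
}

stage_labels <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    as.character(SummarizedExperiment::colData(x)$stage)
  } else {
    stop("stage labels must be supplied for matrix input")
  }
}

# Ordered unique stages: honour factor levels, else sort by embryonic-day
# number parsed from labels like "E11", else lexicographic.
order_stages <- function(stages) {
  if (is.factor(stages)) return(levels(stages)[levels(stages) %in% stages])
  u <- unique(as.character(stages))
  day <- suppressWarnings(as.numeric(sub("^E", "", u)))
  if (!anyNA(day)) u[order(day)] else sort(u)
}
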