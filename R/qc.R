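# Spike-in calibrated detection thresholding and sample quality control.
#
# The platform's proportional-detection limit is the 20-copy spike-in: a
# probe counts as detected in a cell when its signal reaches the median
# signal of that spike across cells (the "Over-20 copies" rule).

#' Detection threshold from the 20-copy spike-in
#'
#' Median signal, across all cells, of the probe carrying the spike-in added
#' at the proportional-detection copy number (20 copies per cell).
#'
#' @param x expression matrix (SummarizedExperiment or matrix, linear scale).
#' @param spike20_probe probe id of the 20-copy spike (default `"spike_20"`,
#'   the generator's id).
#' @param cells optional cell ids/indices over which the median is taken
#'   (e.g. only QC-passing samples).
#' @return Detection threshold in signal units.
#' @export
copy_threshold <- function(x, spike20_probe = "spike_20", cells = NULL) {
  m <- signal_matrix(x)
  if (any(m < 0)) stop("negative signal values: corrupt input")
  if (!spike20_probe %in% rownames(m))
    stop("spike probe '", spike20_probe, "' absent from matrix")
  v <- m[spike20_probe, ]
  if (!is.null(cells)) v <- v[cells]
  median(v)
}

#' Filter probes by the detection threshold
#'
#' A probe is retained iff at least one cell reaches the threshold
#' (max signal >= threshold); row order is preserved.
#'
#' @param x expression matrix (linear scale).
#' @param threshold positive signal threshold, typically [copy_threshold()].
#' @return Character vector of retained probe ids.
#' @export
filter_detected <- function(x, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  m <- signal_matrix(x)
  rownames(m)[apply(m, 1L, max) >= threshold]
}

#' Per-sample spike-in linearity check
#'
#' OLS fit of log2(signal) on log2(copies) per sample, restricted to
#' spike-ins at or above the proportional-detection copy number.  A sample is
#' flagged when its slope leaves `[1 - tol, 1 + tol]` (or when a usable spike
#' signal is non-positive).
#'
#' @param x expression matrix (linear scale).
#' @param spikeins data.frame with columns `probe_id` and `copies`.
#' @param min_copies copy number from which proportionality is expected
#'   (default 20).
#' @param tol slope tolerance (default 0.25).
#' @return data.frame: sample, slope, r_squared, flagged.
#' @export
spike_linearity <- function(x, spikeins, min_copies = 20, tol = 0.25) {
  m <- signal_matrix(x)
  use <- spikeins[spikeins$copies >= min_copies, , drop = FALSE]
  if (length(unique(use$copies)) < 2L)
    stop("need >= 2 distinct spike-in copy levels >= ", min_copies)
  miss <- setdiff(use$probe_id, rownames(m))
  if (length(miss)) stop("spike probes absent: ", paste(miss, collapse = ", "))
  lx <- log2(use$copies)
  sig <- m[use$probe_id, , drop = FALSE]
  res <- t(vapply(seq_len(ncol(sig)), function(j) {
    y <- sig[, j]
    if (any(y <= 0)) return(c(NA_real_, NA_real_))
    fit_xy <- stats::lm.fit(cbind(1, lx), log2(y))
    slope <- fit_xy$coefficients[2]
    ss_res <- sum(fit_xy$residuals^2)
    ss_tot <- sum((log2(y) - mean(log2(y)))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    c(slope, r2)
  }, numeric(2)))
  data.frame(sample = colnames(sig),
             slope = res[, 1], r_squared = res[, 2],
             flagged = is.na(res[, 1]) | abs(res[, 1] - 1) > tol,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample quality control
#'
#' A sample passes when every housekeeping gene is detected (signal >=
#' threshold on arrays; Ct < 40 on qPCR) and, when spike-ins are supplied,
#' its spike linearity flag is clear.  Failures carry reason strings.
#'
#' @param x expression matrix or [qpcr_table()].
#' @param housekeeping character vector of housekeeping gene ids.
#' @param threshold detection threshold (required for array input).
#' @param spikeins optional spike-in data.frame for [spike_linearity()].
#' @param min_copies,tol passed to [spike_linearity()].
#' @return data.frame: sample, pass, reasons (character, `;`-joined).
#' @export
sample_qc <- function(x, housekeeping, threshold = NULL, spikeins = NULL,
                      min_copies = 20, tol = 0.25) {
  if (length(housekeeping) == 0L) stop("housekeeping gene list is empty")
  if (inherits(x, "qpcr_table")) {
    miss <- setdiff(housekeeping, rownames(x$ct))
    if (length(miss))
      stop("housekeeping genes absent: ", paste(miss, collapse = ", "))
    det <- x$detected[housekeeping, , drop = FALSE]
    samples <- colnames(x$ct)
  } else {
    m <- signal_matrix(x)
    miss <- setdiff(housekeeping, rownames(m))
    if (length(miss))
      stop("housekeeping genes absent: ", paste(miss, collapse = ", "))
    if (is.null(threshold))
      stop("threshold is required for array input")
    det <- m[housekeeping, , drop = FALSE] >= threshold
    samples <- colnames(m)
  }
  reasons <- lapply(seq_along(samples), function(j) {
    r <- character(0)
    bad <- housekeeping[!det[, j]]
    if (length(bad))
      r <- paste0("housekeeping undetected: ", bad)
    r
  })
  if (!is.null(spikeins) && !inherits(x, "qpcr_table")) {
    lin <- spike_linearity(x, spikeins, min_copies = min_copies, tol = tol)
    for (j in which(lin$flagged))
      reasons[[j]] <- c(reasons[[j]],
                        sprintf("spike linearity: slope=%s",
                                formatC(lin$slope[j], digits = 3)))
  }
  data.frame(sample = samples,
             pass = lengths(reasons) == 0L,
             reasons = vapply(reasons, paste, "", collapse = "; "),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full spike-in / detection QC report
#'
#' Runs sample QC with a provisional threshold (20-copy spike median over all
#' cells), recomputes the detection threshold over passing samples only, and
#' applies the Over-N probe filter.
#'
#' @param x expression matrix (SummarizedExperiment or matrix).
#' @param spikeins data.frame with `probe_id`, `copies`.
#' @param housekeeping housekeeping gene ids.
#' @param spike20_probe probe id of the 20-copy spike.
#' @param min_copies,tol passed to [spike_linearity()].
#' @return Object of class `qc_report`: list with `copy_threshold`,
#'   `samples` (QC table), `linearity`, `retained` probe ids.
#' @export
qc_report <- function(x, spikeins, housekeeping,
                      spike20_probe = "spike_20",
                      min_copies = 20, tol = 0.25) {
  provisional <- copy_threshold(x, spike20_probe)
  samples <- sample_qc(x, housekeeping, threshold = provisional,
                       spikeins = spikeins, min_copies = min_copies,
                       tol = tol)
  passing <- samples$sample[samples$pass]
  thr <- if (length(passing)) copy_threshold(x, spike20_probe, cells = passing)
         else provisional
  structure(list(copy_threshold = thr,
                 samples = samples,
                 linearity = spike_linearity(x, spikeins,
                                             min_copies = min_copies,
                                             tol = tol),
                 retained = filter_detected(x, thr)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: threshold", formatC(x$copy_threshold, digits = 6),
      "signal units;", sum(x$samples$pass), "/", nrow(x$samples),
      "samples pass;", length(x$retained), "probes retained\n")
  invisible(x)
}
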