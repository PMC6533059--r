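#' Z'-factor of a plate
#'
#' Assay-quality statistic
#' \deqn{Z' = 1 - \frac{3\sigma_{c+} + 3\sigma_{c-}}{|\mu_{c+} - \mu_{c-}|}}
#' computed with sample standard deviations (n - 1 denominator). Values
#' between 0.5 and 1 indicate an excellent high-throughput assay.
#'
#' @param posValues,negValues numeric vectors of well ratios for the
#'   positive and negative controls (>= 2 values each).
#' @return Z'-factor (dimensionless, <= 1).
#' @export
#' @examples
#' zprime(rnorm(8, 10, 1), rnorm(8, 2, 1))
zprime <- function(posValues, negValues) {
  posValues <- posValues[is.finite(posValues)]
  negValues <- negValues[is.finite(negValues)]
  if (length(posValues) < 2L || length(negValues) < 2L)
    stop("need at least 2 finite values per control group")
  sep <- abs(mean(posValues) - mean(negValues))
  if (sep == 0) stop("control group means coincide: Z' undefined")
  1 - (3 * stats::sd(posValues) + 3 * stats::sd(negValues)) / sep
}

#' log2 fold change against the plate's negative-control median
#'
#' @param wellRatio positive well ratio.
#' @param negRatios positive ratios of the same plate's negative-control
#'   wells (>= 1).
#' @return log2(wellRatio / median(negRatios)).
#' @export
#' @examples
#' log2fcVsNegMedian(0.75, c(1, 1, 1))  # log2(3/4)
log2fcVsNegMedian <- function(wellRatio, negRatios) {
  negRatios <- negRatios[is.finite(negRatios)]
  if (length(negRatios) < 1L)
    stop("need at least one negative-control ratio")
  if (any(c(wellRatio, negRatios) <= 0))
    stop("ratios must be positive")
  log2(wellRatio / stats::median(negRatios))
}

#' Paired SSMD across replicates
#'
#' Strictly standardized mean difference of the per-replicate paired
#' differences `d` (here: per-replicate log2 fold changes against the plate
#' negative-control median). The method-of-moments estimate is
#' `mean(d)/sd(d)`; the UMVUE estimate multiplies it by
#' \eqn{\Gamma(\frac{n-1}{2}) / \Gamma(\frac{n-2}{2}) \sqrt{2/(n-1)}},
#' which requires n >= 3. Zero-variance input returns a signed infinity
#' (or 0 when the mean is also 0).
#'
#' @param diffs numeric vector of per-replicate differences (n >= 2; n >= 3
#'   for `umvue`).
#' @param method `"umvue"` (default) or `"mm"`.
#' @return SSMD estimate; its sign equals the sign of `mean(diffs)`.
#' @export
#' @examples
#' ssmdPaired(c(2, 0, 1))            # 1/sqrt(pi)
#' ssmdPaired(c(2, 0, 1), "mm")      # 1
ssmdPaired <- function(diffs, method = c("umvue", "mm")) {
  method <- match.arg(method)
  if (any(!is.finite(diffs))) stop("'diffs' must be finite")
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 replicates")
  if (method == "umvue" && n < 3L)
    stop("the UMVUE estimator is defined only for n >= 3; use method = 'mm'")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    if (m == 0) return(0)
    return(sign(m) * Inf)
  }
  coefU <- if (method == "umvue")
    exp(lgamma((n - 1) / 2) - lgamma((n - 2) / 2)) * sqrt(2 / (n - 1))
  else 1
  coefU * m / s
}

#' Plate-level QC: control summaries and Z'-factor
#'
#' For every (plate, replicate) in a measurement table, summarises the
#' positive and negative comparison groups and computes the Z'-factor. On
#' screen plates the groups are the pooled CHC/dynamin-2 positive-control
#' wells versus the negative-control wells; on robustness plates the
#' stimulated versus unstimulated halves.
#'
#' @param measurements corrected measurement data.frame with columns
#'   `plate_id`, `replicate_id`, `role`, `ratio`.
#' @return data.frame with columns `plate_id`, `replicate_id`, `mu_pos`,
#'   `sigma_pos`, `mu_neg`, `sigma_neg`, `n_pos`, `n_neg`, `zprime`.
#' @export
plateQC <- function(measurements) {
  need <- c("plate_id", "replicate_id", "role", "ratio")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  key <- interaction(measurements$plate_id, measurements$replicate_id,
                     drop = TRUE)
  out <- lapply(split(measurements, key), function(d) {
    if (any(d$role %in% c("stimulated", "unstimulated"))) {
      pos <- d$ratio[d$role == "stimulated"]
      neg <- d$ratio[d$role == "unstimulated"]
    } else {
      pos <- d$ratio[d$role %in% c("positive_chc", "positive_dyn2")]
      neg <- d$ratio[d$role == "negative_control"]
    }
    pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
    if (length(pos) < 2L || length(neg) < 2L) return(NULL)
    data.frame(plate_id = d$plate_id[1], replicate_id = d$replicate_id[1],
               mu_pos = mean(pos), sigma_pos = stats::sd(pos),
               mu_neg = mean(neg), sigma_neg = stats::sd(neg),
               n_pos = length(pos), n_neg = length(neg),
               zprime = zprime(pos, neg), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-target screen analysis
#'
#' Normalises every well to its own plate's negative-control median
#' (per plate, per replicate), then summarises each target across
#' replicates: the per-replicate log2 fold changes, their mean, and the
#' paired SSMD. The CHC and dynamin-2 positive controls are summarised the
#' same way (per plate, averaging their four wells within each replicate)
#' and included as labeled control rows.
#'
#' @param measurements corrected measurement data.frame covering all
#'   replicates of a screen.
#' @param method SSMD estimator passed to [ssmdPaired()] (`"umvue"` needs
#'   >= 3 replicates; with fewer, SSMD is `NA` unless `method = "mm"`).
#' @return List with `results` (one row per target / control group:
#'   `target_id`, `is_control`, `mean_log2fc`, `ssmd`, `n_replicates`),
#'   `perReplicate` (long table of per-well log2 fold changes) and `qc`
#'   (the [plateQC()] table).
#' @export
analyzeScreen <- function(measurements, method = c("umvue", "mm")) {
  method <- match.arg(method)
  m <- measurements[measurements$role %in%
                      c("target", "negative_control", "positive_chc",
                        "positive_dyn2"), ]
  if (nrow(m) == 0L) stop("no screen wells in the measurement table")
  key <- interaction(m$plate_id, m$replicate_id, drop = TRUE)
  normed <- do.call(rbind, lapply(split(m, key), function(d) {
    neg <- d$ratio[d$role == "negative_control" & is.finite(d$ratio)]
    if (length(neg) == 0L)
      stop("plate ", d$plate_id[1], " replicate ", d$replicate_id[1],
           " has no usable negative controls")
    d$log2fc <- vapply(d$ratio, function(r)
      if (is.finite(r) && r > 0) log2fcVsNegMedian(r, neg) else NA_real_,
      numeric(1))
    d
  }))
  rownames(normed) <- NULL
  nReps <- length(unique(normed$replicate_id))
  summarise <- function(values, id, isControl) {
    values <- values[is.finite(values)]
    n <- length(values)
    ssmd <- if (n >= 3L || (n >= 2L && method == "mm"))
      ssmdPaired(values, method) else NA_real_
    data.frame(target_id = id, is_control = isControl,
               mean_log2fc = mean(values), ssmd = ssmd, n_replicates = n,
               stringsAsFactors = FALSE)
  }
  repLevels <- unique(normed$replicate_id)
  tgt <- normed[normed$role == "target", ]
  perTarget <- lapply(split(tgt, tgt$target_id), function(d) {
    cnt <- table(factor(d$replicate_id, levels = repLevels))
    if (any(cnt != 1L))
      stop("target ", d$target_id[1],
           " does not appear exactly once per replicate")
    summarise(d$log2fc, d$target_id[1], FALSE)
  })
  ctl <- normed[normed$role %in% c("positive_chc", "positive_dyn2"), ]
  ctl$group <- ifelse(ctl$role == "positive_chc", "CHC", "DYN2")
  perControl <- lapply(split(ctl, interaction(ctl$group, ctl$plate_id,
                                              drop = TRUE)), function(d) {
    byRep <- vapply(split(d$log2fc, d$replicate_id),
                    mean, numeric(1), na.rm = TRUE)
    summarise(byRep, sprintf("%s:%s", d$group[1], d$plate_id[1]), TRUE)
  })
  results <- do.call(rbind, c(perTarget, perControl))
  rownames(results) <- NULL
  list(results = results, perReplicate = normed, qc = plateQC(measurements))
}

#' Dual-flashlight table
#'
#' Orders the per-target results by mean log2 fold change ascending (most
#' inhibited first) and returns the (mean_log2fc, ssmd) pairs for plotting,
#' with positive controls as labeled rows. Plate QC is attached as the
#' `plate_qc` attribute.
#'
#' @param analysis result of [analyzeScreen()], or its `results`
#'   data.frame.
#' @param qc optional [plateQC()] table (taken from `analysis` when
#'   available).
#' @return data.frame sorted by `mean_log2fc` with columns `target_id`,
#'   `is_control`, `mean_log2fc`, `ssmd`, `n_replicates`.
#' @export
dualFlashlight <- function(analysis, qc = NULL) {
  results <- if (is.data.frame(analysis)) analysis else analysis$results
  if (is.null(qc) && !is.data.frame(analysis)) qc <- analysis$qc
  need <- c("target_id", "mean_log2fc", "ssmd", "n_replicates")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  if (length(unique(results$n_replicates[!results$is_control])) > 1L)
    stop("inconsistent replicate counts across targets")
  out <- results[order(results$mean_log2fc), ]
  rownames(out) <- NULL
  attr(out, "plate_qc") <- qc
  out
}

#' Call screen hits
#'
#' Flags targets whose effect passes both an SSMD and a log2 fold-change
#' cutoff: endocytosis inhibitors (`ssmd <= -ssmdThreshold` and
#' `mean_log2fc <= -log2fcThreshold`) and, symmetrically, enhancers.
#' Control rows are excluded from the returned subset.
#'
#' @param table dual-flashlight table (see [dualFlashlight()]).
#' @param ssmdThreshold SSMD magnitude cutoff (default 1.0).
#' @param log2fcThreshold log2 fold-change magnitude cutoff (default 0.2).
#' @return Subset of target rows with a `flag` column (`"inhibitor"` or
#'   `"enhancer"`).
#' @export
callHits <- function(table, ssmdThreshold = 1.0, log2fcThreshold = 0.2) {
  if (!all(is.finite(c(ssmdThreshold, log2fcThreshold))) &&
      !all(is.infinite(c(ssmdThreshold, log2fcThreshold)) |
             is.finite(c(ssmdThreshold, log2fcThreshold))))
    stop("thresholds must be numeric")
  t <- table[!table$is_control & is.finite(table$mean_log2fc), ]
  inh <- !is.na(t$ssmd) & t$ssmd <= -ssmdThreshold &
    t$mean_log2fc <= -log2fcThreshold
  enh <- !is.na(t$ssmd) & t$ssmd >= ssmdThreshold &
    t$mean_log2fc >= log2fcThreshold
  out <- t[inh | enh, ]
  out$flag <- ifelse(out$ssmd < 0, "inhibitor", "enhancer")
  rownames(out) <- NULL
  out
}

#' Write dual-flashlight and QC tables as CSV
#' @param table dual-flashlight table.
#' @param path file path.
#' @export
writeDualFlashlight <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDualFlashlight
#' @param qc [plateQC()] table.
#' @export
writePlateQC <- function(qc, path) {
  utils::write.csv(qc, path, row.names = FALSE)
  invisible(path)
}
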