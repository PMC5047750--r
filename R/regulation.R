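# Sort-based (order-statistic) quantile, R's type 1.
quantile_type1 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 1, names = FALSE)
}

#' Responder threshold from an unstimulated control
#'
#' "Responder" cells are those whose reporter endpoint exceeds a
#' threshold derived from the endpoint distribution of an unstimulated
#' control: the stated order-statistic quantile (95th percentile by
#' default).
#'
#' @param control Either a `cell_experiment` or a numeric vector of
#'   control endpoint values.
#' @param quantile Probability of the order statistic used as cut.
#' @param min_cells Minimum number of control cells required.
#' @return Object of class `responder_rule` with fields `threshold` and
#'   `source`.
#' @export
derive_responder_threshold <- function(control, quantile = 0.95,
                                       min_cells = 50) {
  ep <- if (inherits(control, "cell_experiment"))
    control$reporter[, ncol(control$reporter)] else as.numeric(control)
  if (length(ep) < min_cells)
    stop(sprintf("control has %d cells; need >= %d", length(ep), min_cells))
  if (quantile <= 0 || quantile > 1) stop("'quantile' must be in (0, 1]")
  structure(list(threshold = quantile_type1(ep, quantile),
                 source = sprintf("control_quantile (q=%g, n=%d)",
                                  quantile, length(ep))),
            class = "responder_rule")
}

#' Fixed absolute responder threshold
#' @param threshold Expression cut, a.u.
#' @return Object of class `responder_rule`.
#' @export
responder_rule_absolute <- function(threshold) {
  structure(list(threshold = threshold, source = "absolute"),
            class = "responder_rule")
}

#' @export
print.responder_rule <- function(x, ...) {
  cat(sprintf("<responder_rule> threshold %.4g a.u. [%s]\n",
              x$threshold, x$source))
  invisible(x)
}

#' Default TF bin edges
#'
#' Five equal-width bins spanning zero to the 99th percentile of the
#' observed TF peak levels.
#'
#' @param tf_values Per-cell TF peak levels.
#' @param n_bins Number of bins.
#' @param upper_quantile Quantile defining the top edge.
#' @return Numeric vector of `n_bins + 1` edges.
#' @export
default_bin_edges <- function(tf_values, n_bins = 5,
                              upper_quantile = 0.99) {
  hi <- quantile_type1(tf_values, upper_quantile)
  if (hi <= 0) stop("cannot bin: non-positive upper edge")
  seq(0, hi, length.out = n_bins + 1L)
}

bin_relationship <- function(xval, expr, responder, bin_edges, tf_label) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  keep <- !is.na(xval) & xval >= bin_edges[1L] &
    xval <= bin_edges[nb + 1L]
  bx <- findInterval(xval[keep], bin_edges, rightmost.closed = TRUE,
                     all.inside = FALSE)
  ex <- expr[keep]; rs <- responder[keep]
  n_per_bin <- tabulate(bx, nbins = nb)
  if (!any(n_per_bin > 0)) stop("no cell falls in any bin")
  xv <- xval[keep]
  bin_means <- responder_fraction <- bin_mean_tf <- rep(NA_real_, nb)
  for (b in which(n_per_bin > 0)) {
    bin_means[b] <- mean(ex[bx == b])
    responder_fraction[b] <- mean(rs[bx == b])
    bin_mean_tf[b] <- mean(xv[bx == b])
  }
  structure(list(tf = tf_label, bin_edges = bin_edges,
                 bin_centers = (bin_edges[-1L] + bin_edges[-(nb + 1L)]) / 2,
                 bin_means = bin_means,
                 bin_mean_tf = bin_mean_tf,
                 responder_fraction = responder_fraction,
                 n_per_bin = n_per_bin,
                 n_retained = sum(n_per_bin),
                 n_excluded = sum(!keep)),
            class = "binned_relationship")
}

#' Bin single-cell expression by TF activity
#'
#' Bins cells by their peak nuclear TF level and reports, per bin, the
#' mean expression and the responder fraction. Cells outside the edges
#' are excluded and counted; empty bins are reported as missing, never
#' as zero.
#'
#' @param features Feature table from [compute_features()].
#' @param tf `"msn2"` or `"msn4"`.
#' @param bin_edges Strictly increasing edges; default
#'   [default_bin_edges()] of the chosen TF peaks.
#' @param responder_rule A `responder_rule`.
#' @param stat Expression statistic: `"endpoint"` (default) or `"max"`.
#' @return Object of class `binned_relationship` with fields `tf`,
#'   `bin_edges`, `bin_centers`, `bin_means`, `responder_fraction`,
#'   `n_per_bin`, `n_retained`, `n_excluded`.
#' @export
bin_by_tf <- function(features, tf = c("msn2", "msn4"), bin_edges = NULL,
                      responder_rule, stat = c("endpoint", "max")) {
  tf <- match.arg(tf)
  stat <- match.arg(stat)
  stopifnot(inherits(responder_rule, "responder_rule"))
  xval <- features[[paste0("peak_", tf)]]
  expr <- features[[if (stat == "endpoint") "expr_endpoint" else "expr_max"]]
  if (is.null(bin_edges)) bin_edges <- default_bin_edges(xval)
  bin_relationship(xval, expr, expr > responder_rule$threshold, bin_edges,
                   tf)
}

#' Expression versus the Msn2:Msn4 nuclear ratio
#'
#' Bins cells by the ratio of peak Msn2 to peak Msn4; cells with
#' non-positive Msn4 peak (ratio undefined) are excluded and counted.
#'
#' @inheritParams bin_by_tf
#' @param bin_edges Strictly increasing ratio edges; default 5
#'   equal-width bins to the 95th percentile of defined ratios.
#' @return A `binned_relationship` with `tf = "ratio_msn2_over_msn4"`.
#' @export
ratio_relationship <- function(features, bin_edges = NULL, responder_rule,
                               stat = c("endpoint", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(responder_rule, "responder_rule"))
  ok <- features$peak_msn4 > 0
  if (!any(ok)) stop("all Msn2:Msn4 ratios are undefined")
  ratio <- ifelse(ok, features$peak_msn2 / features$peak_msn4, NA_real_)
  expr <- features[[if (stat == "endpoint") "expr_endpoint" else "expr_max"]]
  if (is.null(bin_edges)) {
    hi <- quantile_type1(ratio[ok], 0.95)
    bin_edges <- seq(0, hi, length.out = 6L)
  }
  out <- bin_relationship(ratio, expr, expr > responder_rule$threshold,
                          bin_edges, "ratio_msn2_over_msn4")
  out$n_excluded <- out$n_excluded  # includes undefined-ratio cells
  out
}

#' @export
print.binned_relationship <- function(x, ...) {
  cat(sprintf("<binned_relationship> by %s: %d bins, %d cells retained (%d excluded)\n",
              x$tf, length(x$bin_means), x$n_retained, x$n_excluded))
  print(data.frame(center = signif(x$bin_centers, 4),
                   mean_expr = signif(x$bin_means, 4),
                   responder_frac = signif(x$responder_fraction, 3),
                   n = x$n_per_bin))
  invisible(x)
}

#' @export
as.data.frame.binned_relationship <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  data.frame(tf = x$tf,
             bin_lo = x$bin_edges[-length(x$bin_edges)],
             bin_hi = x$bin_edges[-1L],
             bin_center = x$bin_centers,
             mean_expr = x$bin_means,
             responder_fraction = x$responder_fraction,
             n = x$n_per_bin)
}

#' Quantile/mean summary of endpoint distributions by group
#'
#' The numeric summary behind violin-style plots: the 5/25/50/75/95th
#' order-statistic percentiles, the mean, and the group size for each
#' genotype or condition.
#'
#' @param endpoints Numeric vector of expression endpoints.
#' @param group Grouping factor/character, recycled to the endpoints.
#' @return Data frame with one row per group: `group`, `q05`, `q25`,
#'   `q50`, `q75`, `q95`, `mean`, `n`.
#' @export
distribution_summary <- function(endpoints, group = "all") {
  if (!length(endpoints)) stop("empty group")
  group <- rep_len(as.character(group), length(endpoints))
  out <- lapply(split(endpoints, group), function(v) {
    q <- quantile_type1(v, c(.05, .25, .50, .75, .95))
    data.frame(q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5],
               mean = mean(v), n = length(v))
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}
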