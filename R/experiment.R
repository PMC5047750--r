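#' Generate a complete simulated single-cell experiment
#'
#' Composes [sample_tf_traces()] and [simulate_promoter()]: draws latent
#' (noiseless) TF traces and per-cell capacities, integrates the
#' promoter model, then applies additive measurement noise to all three
#' observed channels. The same configuration and seed reproduce the
#' experiment bit-identically.
#'
#' @param tf A [tf_params()].
#' @param prom A [promoter_params()].
#' @param stim A [stimulus_program()].
#' @param genotype One of `genotypes()`.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param label Optional experiment label (stored in metadata and used
#'   for cell ids).
#' @return An object of class `cell_experiment`: matrices `msn2`,
#'   `msn4`, `reporter` (`n_cells x` grid length), vectors `time_min`,
#'   `capacity`, `cell_id`, per-cell `genotype`, and a `meta` list
#'   recording every generating parameter.
#' @examples
#' ex <- generate_experiment(tf_params(), promoter_params("fast"),
#'                           stimulus_program("pulse"), "WT",
#'                           n_cells = 10, seed = 1)
#' ex
#' @export
generate_experiment <- function(tf = tf_params(),
                                prom = promoter_params("slow"),
                                stim = stimulus_program("pulse"),
                                genotype = "WT", n_cells = 300,
                                seed = 1, label = NULL) {
  stopifnot(inherits(tf, "tf_params"), inherits(prom, "promoter_params"),
            inherits(stim, "stimulus_program"))
  if (!genotype %in% genotypes()) stop("unknown genotype: ", genotype)
  set.seed(seed)
  lat <- sample_tf_traces(tf, stim, genotype, n_cells, seed = NULL,
                          noise = FALSE)
  reporter <- simulate_promoter(lat$msn2, lat$msn4, lat$capacity, prom,
                                lat$time_min)
  if (is.null(dim(reporter))) reporter <- matrix(reporter, nrow = 1)

  # noise is drawn for every channel regardless of genotype so the RNG
  # stream is identical across genotypes (deletion = zeroing, not skipping)
  msn2 <- lat$msn2; msn4 <- lat$msn4
  sd <- tf$meas_noise_sd
  add_noise <- function(X) X + matrix(stats::rnorm(length(X), 0, sd),
                                      nrow = nrow(X))
  msn2 <- add_noise(msn2)
  msn4 <- add_noise(msn4)
  reporter <- add_noise(reporter)
  if (genotype %in% c("msn2d", "msn2d_msn4d")) msn2[] <- 0
  if (genotype %in% c("msn4d", "msn2d_msn4d")) msn4[] <- 0

  if (is.null(label))
    label <- paste(prom$kinetics_class, genotype, format(stim), sep = "_")
  structure(
    list(time_min = lat$time_min, msn2 = msn2, msn4 = msn4,
         reporter = reporter, capacity = lat$capacity,
         cell_id = sprintf("%s_c%04d", label, seq_len(nrow(msn2))),
         genotype = rep(genotype, nrow(msn2)),
         meta = list(label = label, genotype = genotype,
                     promoter = prom$kinetics_class, stim = stim,
                     tf = tf, prom = prom, n_cells = as.integer(n_cells),
                     seed = as.integer(seed))),
    class = "cell_experiment")
}

#' Number of cells in an experiment
#' @param x A `cell_experiment`.
#' @return Integer cell count.
#' @export
n_cells <- function(x) {
  stopifnot(inherits(x, "cell_experiment"))
  nrow(x$msn2)
}

#' @export
print.cell_experiment <- function(x, ...) {
  cat(sprintf("<cell_experiment> '%s': %d cells x %d samples (%g..%g min)\n",
              x$meta$label, nrow(x$msn2), length(x$time_min),
              min(x$time_min), max(x$time_min)))
  cat(sprintf("  genotype %s, %s promoter, stimulus %s\n",
              x$meta$genotype, x$meta$promoter, format(x$meta$stim)))
  invisible(x)
}

#' @export
summary.cell_experiment <- function(object, ...) {
  ep <- object$reporter[, ncol(object$reporter)]
  cat(sprintf("'%s': %d cells; mean endpoint %.2f a.u. (sd %.2f)\n",
              object$meta$label, length(ep), mean(ep), stats::sd(ep)))
  invisible(data.frame(label = object$meta$label, n = length(ep),
                       mean_endpoint = mean(ep), sd_endpoint = stats::sd(ep)))
}

#' Long-format table of an experiment
#'
#' @param x A `cell_experiment`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @return Data frame with columns `cell_id`, `genotype`, `promoter`,
#'   `stimulus`, `time_min`, `channel`, `value` (channel in
#'   `msn2`/`msn4`/`reporter`).
#' @export
as.data.frame.cell_experiment <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  n <- nrow(x$msn2); Tn <- length(x$time_min)
  one <- function(mat, channel)
    data.frame(cell_id = rep(x$cell_id, times = Tn),
               genotype = rep(x$genotype, times = Tn),
               promoter = x$meta$promoter,
               stimulus = format(x$meta$stim),
               time_min = rep(x$time_min, each = n),
               channel = channel,
               value = as.vector(mat))
  rbind(one(x$msn2, "msn2"), one(x$msn4, "msn4"),
        one(x$reporter, "reporter"))
}

#' Plot ensemble mean traces of an experiment
#'
#' Base-graphics overview: mean +/- SD envelopes of the two TF channels
#' and of the reporter.
#'
#' @param x A `cell_experiment`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.cell_experiment <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tm <- x$time_min
  m2 <- colMeans(x$msn2); m4 <- colMeans(x$msn4)
  graphics::matplot(tm, cbind(m2, m4), type = "l", lty = 1,
                    col = c("firebrick", "goldenrod"),
                    xlab = "time (min)", ylab = "nuclear level (norm. a.u.)",
                    main = x$meta$label, ...)
  graphics::legend("topright", c("Msn2", "Msn4"), lty = 1, bty = "n",
                   col = c("firebrick", "goldenrod"))
  mr <- colMeans(x$reporter); sr <- apply(x$reporter, 2, stats::sd)
  graphics::plot(tm, mr, type = "l", col = "steelblue",
                 ylim = range(c(mr - sr, mr + sr)),
                 xlab = "time (min)", ylab = "reporter (a.u.)",
                 main = "reporter")
  graphics::lines(tm, mr + sr, lty = 3, col = "steelblue")
  graphics::lines(tm, mr - sr, lty = 3, col = "steelblue")
  invisible(x)
}
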