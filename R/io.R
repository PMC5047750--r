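trace_header <- c("cell_id", "genotype", "promoter", "stimulus",
                  "time_min", "channel", "value")
trace_channels <- c("msn2", "msn4", "reporter")
schema_version <- 1L

#' Write an experiment as a long-format trace CSV
#'
#' Columns (exact header): `cell_id,genotype,promoter,stimulus,time_min,
#' channel,value`, channel in `msn2`/`msn4`/`reporter`.
#'
#' @param experiment A `cell_experiment`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(experiment, path) {
  df <- as.data.frame(experiment)
  df$value <- formatC(df$value, digits = 10, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_stim_label <- function(label, total_min, sample_interval_min) {
  if (grepl("^pulse", label)) {
    m <- regmatches(label, regexec("^pulse([0-9.]+)min_d([0-9.]+)$", label))[[1]]
    if (length(m) != 3L) stop("unparseable stimulus label: ", label)
    stimulus_program("pulse", dose = as.numeric(m[3]),
                     duration_min = as.numeric(m[2]),
                     total_min = total_min,
                     sample_interval_min = sample_interval_min)
  } else {
    m <- regmatches(label, regexec("^(adaptive_transient|sustained)_d([0-9.]+)$",
                                   label))[[1]]
    if (length(m) != 3L) stop("unparseable stimulus label: ", label)
    stimulus_program(m[2], dose = as.numeric(m[3]), total_min = total_min,
                     sample_interval_min = sample_interval_min)
  }
}

#' Read a long-format trace CSV back into a `cell_experiment`
#'
#' Validates the exact header, the channel enum and that every cell is
#' sampled on the same uniform grid; a cell with a missing timepoint is
#' reported by id. An empty file with a valid header yields an empty
#' experiment with a warning.
#'
#' @param path CSV written by [write_traces()] (or of the same schema).
#' @return A `cell_experiment` (without generator parameter metadata;
#'   the stimulus program is reconstructed from its label).
#' @export
read_traces <- function(path) {
  hd <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  if (!identical(names(hd), trace_header))
    stop("header mismatch: expected ", paste(trace_header, collapse = ","))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    warning("empty trace file: ", path)
    return(structure(list(time_min = numeric(), msn2 = matrix(0, 0, 0),
                          msn4 = matrix(0, 0, 0),
                          reporter = matrix(0, 0, 0),
                          capacity = numeric(), cell_id = character(),
                          genotype = character(),
                          meta = list(label = basename(path))),
                     class = "cell_experiment"))
  }
  bad <- setdiff(unique(df$channel), trace_channels)
  if (length(bad)) stop("unknown channel: ", paste(bad, collapse = ", "))
  times <- sort(unique(df$time_min))
  if (length(times) > 2L) {
    dtv <- diff(times)
    if (max(dtv) - min(dtv) > 1e-8) stop("non-uniform time grid")
  }
  cells <- unique(df$cell_id)
  n <- length(cells); Tn <- length(times)
  mats <- lapply(trace_channels, function(ch) matrix(NA_real_, n, Tn))
  names(mats) <- trace_channels
  ti <- match(df$time_min, times)
  ci <- match(df$cell_id, cells)
  for (ch in trace_channels) {
    sel <- df$channel == ch
    mats[[ch]][cbind(ci[sel], ti[sel])] <- df$value[sel]
  }
  for (ch in trace_channels) {
    miss <- which(rowSums(is.na(mats[[ch]])) > 0)
    if (length(miss))
      stop(sprintf("cell '%s' is missing %s timepoints", cells[miss[1L]], ch))
  }
  geno <- df$genotype[match(cells, df$cell_id)]
  stim <- parse_stim_label(df$stimulus[1L], max(times),
                           if (Tn > 1) times[2L] - times[1L] else 2)
  structure(list(time_min = times, msn2 = mats$msn2, msn4 = mats$msn4,
                 reporter = mats$reporter, capacity = rep(NA_real_, n),
                 cell_id = cells, genotype = geno,
                 meta = list(label = basename(path),
                             genotype = if (length(unique(geno)) == 1L)
                               geno[1L] else "mixed",
                             promoter = df$promoter[1L], stim = stim)),
            class = "cell_experiment")
}

#' Write per-cell features as TSV
#' @param features Data frame from [compute_features()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a features TSV
#' @param path TSV written by [write_features()].
#' @return Data frame of per-cell features.
#' @export
read_features <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an experiment manifest as JSON
#'
#' The manifest lists labelled experiment entries (genotype, promoter,
#' stimulus, file paths, seed) under a schema version; labels must be
#' unique.
#'
#' @param entries List of entry lists (fields `label`, `genotype`,
#'   `promoter`, `stimulus`, `traces_path`, `features_path`, `seed`).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(entries, path) {
  labs <- vapply(entries, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("manifest labels must be unique")
  jsonlite::write_json(list(schema_version = schema_version,
                            entries = entries),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(path)
}

#' Read an experiment manifest
#' @param path JSON written by [write_manifest()].
#' @return List with `schema_version` and `entries`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(m$schema_version) || m$schema_version > schema_version)
    stop("unsupported manifest schema version")
  labs <- vapply(m$entries, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("manifest labels must be unique")
  m
}
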