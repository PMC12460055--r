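## Per-step metrics in YAML, plus aggregation across runs.

#' Construct a step-metrics record
#'
#' @param step Step name (e.g. "compress", "cluster").
#' @param parameters Named list of parameters the step ran with.
#' @param values Named list of scalar metrics (or lists of scalars).
#' @param timestamp Timestamp string; defaults to the current time.
#' @return A list with class \code{"stepMetrics"}.
#' @export
stepMetrics <- function(step, parameters = list(), values = list(),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stopifnot(is.character(step), length(step) == 1L)
  if (anyDuplicated(names(values)))
    stop("metric keys must be unique per step", call. = FALSE)
  structure(list(step = step, timestamp = timestamp,
                 parameters = parameters, values = values),
            class = "stepMetrics")
}

## sort keys recursively for diff-stable output
sortKeys <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x)) && length(x))
    x <- x[order(names(x), method = "radix")]
  lapply(x, sortKeys)
}

#' Write a step-metrics record as YAML
#'
#' Keys are emitted in sorted order so output is diff-stable; the document
#' round-trips losslessly through [readMetrics()].
#'
#' @param m A record from [stepMetrics()].
#' @param destination File path; typically
#'   \code{<run>/metrics/<step>.yaml}.
#' @return Invisibly, \code{destination}.
#' @export
writeMetrics <- function(m, destination) {
  stopifnot(inherits(m, "stepMetrics"))
  doc <- list(step = m$step, timestamp = m$timestamp,
              parameters = sortKeys(m$parameters),
              values = sortKeys(m$values))
  dir.create(dirname(destination), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(doc, destination)
  invisible(destination)
}

#' Read a step-metrics YAML document
#'
#' @param source File path.
#' @return A \code{"stepMetrics"} record.
#' @export
readMetrics <- function(source) {
  doc <- yaml::read_yaml(source)
  stepMetrics(doc$step, parameters = doc$parameters, values = doc$values,
              timestamp = doc$timestamp)
}

#' Aggregate metrics from many runs into one TSV table
#'
#' Gathers the requested metric keys from every run directory (searching its
#' \code{metrics/*.yaml} documents) into one row per run. Missing keys give
#' empty cells; a directory without metrics gives a row of empty cells plus a
#' warning.
#'
#' @param runDirs Character vector of run directories.
#' @param fields Character vector of metric keys to collect (searched in each
#'   step's \code{values}; a "step.key" form restricts to one step).
#' @param out Optional output TSV path.
#' @return The table as a data.frame (invisibly written to \code{out} when
#'   given). Row order equals input order.
#' @export
aggregateTable <- function(runDirs, fields, out = NULL) {
  rows <- lapply(runDirs, function(rd) {
    files <- sort(list.files(file.path(rd, "metrics"), pattern = "\\.ya?ml$",
                             full.names = TRUE), method = "radix")
    if (!length(files))
      files <- sort(list.files(rd, pattern = "\\.ya?ml$", full.names = TRUE),
                    method = "radix")
    vals <- character(length(fields)); names(vals) <- fields
    if (!length(files)) {
      warning("no metrics found in ", rd)
    } else {
      docs <- lapply(files, yaml::read_yaml)
      for (f in fields) {
        stepSel <- NULL; key <- f
        if (grepl(".", f, fixed = TRUE)) {
          stepSel <- sub("\\..*$", "", f)
          key <- sub("^[^.]*\\.", "", f)
        }
        for (doc in docs) {
          if (!is.null(stepSel) && !identical(doc$step, stepSel)) next
          v <- doc$values[[key]]
          if (!is.null(v)) {
            vals[[f]] <- paste(unlist(v), collapse = ",")
            break
          }
        }
      }
    }
    c(run = basename(normalizePath(rd, mustWork = FALSE)), vals)
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
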