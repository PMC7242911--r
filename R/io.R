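#' Read and validate a time-series trace
#'
#' Reads a CSV with a leading time column and one or more signal columns,
#' checks that all cells are numeric and that time is strictly
#' increasing, and returns a typed tibble. Column names carry the units
#' (e.g. `time_s`, `fluorescence`); ambiguous files are rejected rather
#' than guessed.
#'
#' @param path Path to a CSV file.
#' @param time_col Name of the time column; defaults to the first column.
#' @return A tibble with the file's columns.
#' @export
read_trace <- function(path, time_col = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(df) < 2L) {
    abort("A trace needs a time column and at least one signal column.")
  }
  time_col <- time_col %||% names(df)[1]
  if (!time_col %in% names(df)) {
    abort(sprintf("Time column `%s` not found.", time_col))
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort(sprintf("Non-numeric value in column `%s`, row %d.", col,
                    bad %||% 1L))
    }
  }
  check_time_increasing(df[[time_col]], time_col)
  df
}

#' Assemble an assay report
#'
#' A serializable record of any fit or summary in the package:
#' parameters with standard errors and units, quality flags, and a
#' provenance block (inputs, seed, package version, timestamp) so a run
#' can be reproduced from the report alone.
#'
#' @param assay One of `"mst_binding"`, `"dose_response"`, `"stopflow"`,
#'   `"quench"`, `"accumulation"`, `"tissue"`, `"stats"`.
#' @param parameters Named list; each element a list with `value` and
#'   optionally `se` and `unit`.
#' @param flags Character vector of quality flags.
#' @param seed Seed used for any randomness (or `NA`).
#' @param inputs Character vector of input identifiers/paths.
#' @return An object of class `assay_report`.
#' @export
assay_report <- function(assay, parameters, flags = character(),
                         seed = NA_integer_, inputs = character()) {
  assay <- match.arg(assay, c("mst_binding", "dose_response", "stopflow",
                              "quench", "accumulation", "tissue", "stats"))
  stopifnot(is.list(parameters), !is.null(names(parameters)))
  structure(
    list(assay = assay, parameters = parameters, flags = flags,
         provenance = list(
           inputs = inputs, seed = seed,
           package_version = as.character(utils::packageVersion("aquassay")),
           timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
         )),
    class = "assay_report"
  )
}

#' Write an assay report to JSON
#'
#' @param report An [assay_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_report <- function(report, path) {
  stopifnot(inherits(report, "assay_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an assay report from JSON
#'
#' @param path Path written by [write_assay_report()].
#' @return An [assay_report()].
#' @export
read_assay_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$flags <- as.character(unlist(x$flags))
  x$provenance$inputs <- as.character(unlist(x$provenance$inputs))
  x$provenance$seed <- if (is.null(x$provenance$seed)) NA_integer_ else
    as.integer(x$provenance$seed)
  class(x) <- "assay_report"
  x
}

# stage registry for run_pipeline
.pipeline_stages <- function() {
  list(
    simulate_mst = function(args) {
      design <- do.call(mst_design, args$design)
      series <- gen_mst_titration(
        s1 = args$s1, s2 = args$s2, kd = args$kd, design = design,
        n_replicates = args$n_replicates %||% 1,
        no_binding = isTRUE(args$no_binding)
      )
      list(data = series, report = NULL)
    },
    fit_binding = function(args) {
      fit <- fit_binding(args$data, p_tot = args$p_tot)
      rep <- assay_report(
        "mst_binding",
        parameters = list(
          s1 = list(value = fit$s1, se = fit$se_s1),
          s2 = list(value = fit$s2, se = fit$se_s2),
          kd = list(value = fit$kd, se = fit$se_kd, unit = "uM")
        ),
        flags = c(if (!fit$converged) "non_converged",
                  if (!fit$binding_detected) "no_binding"),
        seed = args$seed %||% NA_integer_
      )
      list(data = fit, report = rep)
    },
    z_test = function(args) {
      res <- z_test_estimates(args$x1, args$sd1, args$x2, args$sd2,
                              tail = args$tail %||% "one")
      rep <- assay_report(
        "stats",
        parameters = list(z = list(value = res$z),
                          p = list(value = res$p)),
        flags = if (res$infinite_z) "infinite_z" else character()
      )
      list(data = res, report = rep)
    }
  )
}

#' Run a configured analysis pipeline
#'
#' Executes a list of stages in order; each stage receives its own
#' arguments plus, as `data`, the data produced by the previous stage
#' (so `simulate_mst` can feed `fit_binding`). Reports are written to
#' `out_dir` as each stage completes, so earlier reports survive a later
#' failure.
#'
#' @param config A list with element `stages`: a list of
#'   `list(stage = <name>, args = list(...))`. Valid stage names are
#'   `simulate_mst`, `fit_binding`, `z_test`.
#' @param out_dir Optional directory for per-stage JSON reports.
#' @return A named list of [assay_report()]s (stages without a report are
#'   omitted). An empty stage list is a no-op returning an empty list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stages <- config$stages %||% list()
  registry <- .pipeline_stages()
  reports <- list()
  carry <- NULL
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (is.null(st$stage) || !st$stage %in% names(registry)) {
      abort(sprintf("Unknown stage `%s`. Valid stages: %s.",
                    st$stage %||% "<missing>",
                    paste(names(registry), collapse = ", ")))
    }
    args <- st$args %||% list()
    if (!is.null(carry) && is.null(args$data)) args$data <- carry
    res <- registry[[st$stage]](args)
    carry <- res$data
    if (!is.null(res$report)) {
      nm <- sprintf("%02d_%s", i, st$stage)
      reports[[nm]] <- res$report
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_assay_report(res$report, file.path(out_dir,
                                                 paste0(nm, ".json")))
      }
    }
  }
  reports
}
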