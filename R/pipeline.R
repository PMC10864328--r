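#' Write / read a correlation table
#'
#' TSV with one `# site <label>` block per correlation function, columns
#' `lag_ps`, `value`.
#'
#' @param cfs named list of [correlation_function()] objects.
#' @param path file path.
#' @return `path` invisibly / a named list of correlation functions.
#' @export
write_correlation_table <- function(cfs, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cf in cfs) {
    stopifnot(inherits(cf, "correlation_function"))
    writeLines(paste0("# site ", cf$site_label), con)
    writeLines("lag_ps\tvalue", con)
    writeLines(sprintf("%.12g\t%.12g", cf$lags, cf$values), con)
  }
  invisible(path)
}

#' @rdname write_correlation_table
#' @export
read_correlation_table <- function(path) {
  blocks <- .read_site_blocks(path, c("lag_ps", "value"))
  out <- lapply(names(blocks), function(lab) {
    m <- blocks[[lab]]
    correlation_function(m[, 1], m[, 2], site_label = lab, value_tol = 0.1)
  })
  stats::setNames(out, names(blocks))
}

#' Write / read a spectral-fit table
#'
#' TSV with one `# site <label>` block per fit, columns `tau_ps`, `weight`
#' (all grid points, including zeros, so the grid round-trips).
#'
#' @param fits named list of `expfit` objects.
#' @param path file path.
#' @return `path` invisibly / a named list of `expfit` objects.
#' @export
write_fit_table <- function(fits, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (f in fits) {
    stopifnot(inherits(f, "expfit"))
    writeLines(paste0("# site ", f$site_label), con)
    writeLines("tau_ps\tweight", con)
    writeLines(sprintf("%.12g\t%.12g", f$grid$taus, f$weights), con)
  }
  invisible(path)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) {
  blocks <- .read_site_blocks(path, c("tau_ps", "weight"))
  out <- lapply(names(blocks), function(lab) {
    m <- blocks[[lab]]
    taus <- m[, 1]
    g <- timescale_grid(length(taus), taus[1L], taus[length(taus)])
    if (max(abs(g$taus - taus) / taus) > 1e-6)
      stop(sprintf("fit table block '%s' is not on a log-equidistant grid", lab))
    expfit(m[, 2], g, site_label = lab)
  })
  stats::setNames(out, names(blocks))
}

.read_site_blocks <- function(path, cols) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list(); cur_lab <- NULL; cur <- list()
  flush <- function() {
    if (!is.null(cur_lab)) out[[cur_lab]] <<- do.call(rbind, cur)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^#\\s*site\\s+", line)) {
      flush(); cur_lab <- trimws(sub("^#\\s*site\\s+", "", line)); cur <- list()
      next
    }
    if (grepl("^\\s*(#|$)", line)) next
    if (grepl(paste0("^", cols[1L], "\\b"), line)) next
    fields <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
    if (length(fields) != length(cols) || any(is.na(fields)))
      stop(sprintf("parse error at line %d of '%s'", i, path))
    cur[[length(cur) + 1L]] <- fields
  }
  flush()
  if (!length(out)) stop(sprintf("no '# site' blocks found in '%s'", path))
  out
}

#' Write a relaxation table
#'
#' @param results list of `relaxation_result` objects.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_relaxation_table <- function(results, path) {
  df <- do.call(rbind, lapply(results, as.data.frame))
  utils::write.table(format(df, digits = 9, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full relaxation pipeline
#'
#' Executes read -> correlate -> fit -> slow-weight filter -> Redfield ->
#' landscape on a bond-vector table, writing every intermediate as an
#' inspectable TSV plus a JSON run manifest (configuration echo, package
#' version, output checksums). Re-running an identical configuration
#' produces bit-identical outputs.
#'
#' @param config a named list or a path to a YAML file with fields:
#'   `vectors` (path to a vector table, required), `out_dir` (required),
#'   `nucleus` ("15N" or "2H"), `field_mhz`, `grid` (preset name or list
#'   `n`/`tau_min`/`tau_max`), `max_lag_fraction`, `slow_threshold`,
#'   `merge_k`, `constants` (named overrides for [nucleus_constants()]).
#' @return Invisibly, a list with `fits`, `relaxation` (data frame),
#'   `landscape`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  need <- function(field) {
    if (is.null(config[[field]])) stop(sprintf("config field '%s' is required", field))
    config[[field]]
  }
  vec_path <- need("vectors")
  out_dir <- need("out_dir")
  nucleus <- config$nucleus %||% "15N"
  if (!nucleus %in% c("15N", "2H"))
    stop(sprintf("unknown nucleus '%s' in config field 'nucleus'", nucleus))
  field <- field_spec(config$field_mhz %||% 850,
                      config$temperature %||% NA_real_)
  grid <- if (is.null(config$grid)) timescale_grid("NH")
          else if (is.character(config$grid)) timescale_grid(config$grid)
          else timescale_grid(config$grid$n, config$grid$tau_min, config$grid$tau_max)
  slow_threshold <- config$slow_threshold %||% 0.01
  merge_k <- config$merge_k %||% 5L
  const_args <- c(list(nucleus = nucleus), config$constants)
  constants <- do.call(nucleus_constants, const_args)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.2f s", name, proc.time()[["elapsed"]] - t0))
    res
  }

  vt <- stage("read", read_vector_table(vec_path))
  cfs <- stage("correlate",
               p2_autocorrelation(vt, max_lag_fraction = config$max_lag_fraction))
  fits <- stage("fit", lapply(cfs, fit_exponentials, grid = grid,
                              subsample = config$subsample))
  fits <- stage("filter", lapply(fits, filter_artificial_slow,
                                 weight_threshold = slow_threshold))
  relax_fun <- if (nucleus == "15N") relaxation_15N else relaxation_2H
  relax <- stage("relax", lapply(fits, relax_fun, field = field,
                                 constants = constants))
  ls <- stage("landscape",
              merge_consecutive(assemble_landscape(fits), merge_k))

  files <- c(corr = file.path(out_dir, "corr.tsv"),
             fit = file.path(out_dir, "fit.tsv"),
             relax = file.path(out_dir, "relax.tsv"),
             landscape = file.path(out_dir, "landscape.tsv"))
  write_correlation_table(cfs, files[["corr"]])
  write_fit_table(fits, files[["fit"]])
  write_relaxation_table(relax, files[["relax"]])
  write_landscape_table(ls, files[["landscape"]])

  manifest <- list(config = config,
                   package = "spinscape",
                   version = as.character(packageVersion("spinscape")),
                   checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fits = fits,
                 relaxation = do.call(rbind, lapply(relax, as.data.frame)),
                 landscape = ls,
                 files = c(files, manifest = file.path(out_dir, "manifest.json"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
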