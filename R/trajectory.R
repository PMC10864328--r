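#' Bond-vector trajectory
#'
#' Container for time series of unit bond vectors (e.g. backbone N-H) for one
#' or more labelled sites, sampled on a uniform time grid. This is the input
#' of the rotational-correlation machinery, which assumes a constant frame
#' spacing `dt`.
#'
#' @param times numeric vector of frame times in ps, strictly increasing with
#'   uniform spacing (relative tolerance 1e-9).
#' @param vectors named list with one `n_frames x 3` numeric matrix per site;
#'   every row must have Euclidean norm 1 within `norm_tol`.
#' @param site_labels optional character vector of site labels; defaults to
#'   `names(vectors)`.
#' @param normalize if `TRUE`, rows are renormalized to unit length instead of
#'   erroring on small deviations (rows with norm deviating more than 0.1 from
#'   1 are always an error).
#' @param norm_tol tolerance on the unit-norm invariant (default 1e-6).
#'
#' @return An object of class `vector_trajectory` with fields `times`,
#'   `vectors`, `site_labels`, `n_frames`, `dt`.
#' @export
vector_trajectory <- function(times, vectors, site_labels = names(vectors),
                              normalize = FALSE, norm_tol = 1e-6) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("'times' must be non-empty")
  if (!is.list(vectors) || length(vectors) < 1L)
    stop("'vectors' must be a non-empty list of n x 3 matrices")
  if (is.null(site_labels)) site_labels <- paste0("site", seq_along(vectors))
  site_labels <- as.character(site_labels)
  if (length(site_labels) != length(vectors))
    stop("length of 'site_labels' must match 'vectors'")

  n <- length(times)
  if (n >= 2L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("'times' must be strictly increasing")
    dt <- dts[1L]
    if (any(abs(dts - dt) > 1e-9 * max(abs(dt), 1)))
      stop("non-uniform frame spacing: the correlation machinery assumes uniform dt")
  } else {
    dt <- NA_real_
  }

  vectors <- lapply(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    if (is.data.frame(v)) v <- as.matrix(v)
    if (!is.matrix(v) || ncol(v) != 3L)
      stop(sprintf("vectors for site '%s' must be an n x 3 matrix", site_labels[i]))
    storage.mode(v) <- "double"
    if (nrow(v) != n)
      stop(sprintf("site '%s' has %d frames; expected %d (all sites share the time grid)",
                   site_labels[i], nrow(v), n))
    nrm <- sqrt(rowSums(v^2))
    if (any(!is.finite(nrm)) || any(abs(nrm - 1) > 0.1))
      stop(sprintf("site '%s' contains vectors with norm deviating > 0.1 from 1",
                   site_labels[i]))
    if (normalize) {
      v <- v / nrm
    } else if (any(abs(nrm - 1) > norm_tol)) {
      stop(sprintf("site '%s' contains non-unit vectors (max |norm - 1| = %.3g); use normalize = TRUE",
                   site_labels[i], max(abs(nrm - 1))))
    }
    dimnames(v) <- list(NULL, c("x", "y", "z"))
    v
  })
  names(vectors) <- site_labels

  structure(
    list(times = times, vectors = vectors, site_labels = site_labels,
         n_frames = n, dt = dt),
    class = "vector_trajectory"
  )
}

#' @export
print.vector_trajectory <- function(x, ...) {
  cat(sprintf("<vector_trajectory> %d site(s), %d frames, dt = %g ps (%.4g ns total)\n",
              length(x$site_labels), x$n_frames, x$dt,
              (x$n_frames - 1) * x$dt / 1000))
  cat("  sites:", paste(head(x$site_labels, 8L), collapse = ", "),
      if (length(x$site_labels) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Write a bond-vector table
#'
#' Plain-text TSV dialect: one block per site, started by a line
#' `# site <label>`, followed by a `time_ps  x  y  z` header and one row per
#' frame. UTF-8, '.' decimal, '#' comments.
#'
#' @param vt a [vector_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vector_table <- function(vt, path) {
  stopifnot(inherits(vt, "vector_trajectory"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.12g", x)
  for (lab in vt$site_labels) {
    writeLines(paste0("# site ", lab), con)
    writeLines("time_ps\tx\ty\tz", con)
    v <- vt$vectors[[lab]]
    writeLines(paste(fmt(vt$times), fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3]),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bond-vector table
#'
#' Reads the TSV dialect written by [write_vector_table()]. Vectors are
#' re-normalized to unit length on read; a warning is emitted if any norm
#' deviates from 1 by more than 1e-3, and a norm deviating by more than 0.1
#' is a hard error.
#'
#' @param path input file path.
#' @return A [vector_trajectory()].
#' @export
read_vector_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  labs <- character()
  vecs <- list()
  times_ref <- NULL
  cur_lab <- NULL
  cur <- NULL
  flush_block <- function() {
    if (is.null(cur_lab)) return()
    if (length(cur) == 0L)
      stop(sprintf("site block '%s' contains no data rows", cur_lab))
    m <- do.call(rbind, cur)
    if (is.null(times_ref)) {
      times_ref <<- m[, 1]
    } else if (nrow(m) != length(times_ref) ||
               any(abs(m[, 1] - times_ref) > 1e-9 * pmax(abs(times_ref), 1))) {
      stop(sprintf("site block '%s' has a different time grid than earlier blocks", cur_lab))
    }
    labs <<- c(labs, cur_lab)
    vecs[[cur_lab]] <<- m[, 2:4, drop = FALSE]
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^#\\s*site\\s+", line)) {
      flush_block()
      cur_lab <- sub("^#\\s*site\\s+", "", line)
      cur_lab <- trimws(cur_lab)
      cur <- list()
      next
    }
    if (grepl("^\\s*(#|$)", line)) next
    if (grepl("^time_ps\\b", line)) next
    if (is.null(cur_lab))
      stop(sprintf("parse error at line %d: data row before any '# site' header", i))
    fields <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(fields) != 4L)
      stop(sprintf("parse error at line %d: expected 4 fields, found %d", i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(sprintf("parse error at line %d: non-numeric field", i))
    cur[[length(cur) + 1L]] <- vals
  }
  flush_block()
  if (length(labs) == 0L) stop("no '# site' blocks found in file")

  dev <- vapply(vecs, function(v) max(abs(sqrt(rowSums(v^2)) - 1)), numeric(1))
  if (any(dev > 0.1))
    stop(sprintf("vector norms deviate from 1 by up to %.3g (> 0.1)", max(dev)))
  if (any(dev > 1e-3))
    warning(sprintf("vector norms deviate from 1 by up to %.3g; re-normalizing", max(dev)))
  vector_trajectory(times_ref, vecs, labs, normalize = TRUE)
}

# --- secondary-structure trajectories ---------------------------------------

.dssp_alphabet <- c("H", "G", "I", "E", "B", "T", "S", "~")

#' Secondary-structure trajectory
#'
#' A rectangular frames-by-residues matrix of one-letter DSSP codes
#' (H, G, I, E, B, T, S, `~`).
#'
#' @param codes character matrix (frames x residues) of one-letter codes.
#' @param residue_labels optional residue labels; defaults to column names.
#' @return An object of class `ss_trajectory`.
#' @export
ss_trajectory <- function(codes, residue_labels = colnames(codes)) {
  if (!is.matrix(codes)) stop("'codes' must be a character matrix")
  storage.mode(codes) <- "character"
  bad <- setdiff(unique(as.vector(codes)), .dssp_alphabet)
  if (length(bad))
    stop(sprintf("unknown secondary-structure code(s): %s",
                 paste(sQuote(bad), collapse = ", ")))
  if (is.null(residue_labels)) residue_labels <- paste0("res", seq_len(ncol(codes)))
  colnames(codes) <- residue_labels
  structure(list(codes = codes, residue_labels = residue_labels,
                 n_frames = nrow(codes)),
            class = "ss_trajectory")
}

#' @export
print.ss_trajectory <- function(x, ...) {
  cat(sprintf("<ss_trajectory> %d frames x %d residues\n",
              nrow(x$codes), ncol(x$codes)))
  invisible(x)
}

#' Read / write a secondary-structure table
#'
#' Whitespace-separated table with a residue-label header row, then one row
#' of one-letter DSSP codes per frame.
#'
#' @param path file path.
#' @return [read_ss_table()] returns an [ss_trajectory()];
#'   [write_ss_table()] returns `path` invisibly.
#' @export
read_ss_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2L) stop("secondary-structure table needs a header and at least one frame row")
  header <- strsplit(trimws(lines[idx[1L]]), "\\s+")[[1]]
  nres <- length(header)
  rows <- lapply(idx[-1L], function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != nres)
      stop(sprintf("parse error at line %d: %d codes, expected %d (ragged row)",
                   i, length(fields), nres))
    bad <- fields[nchar(fields) != 1L | !(fields %in% .dssp_alphabet)]
    if (length(bad))
      stop(sprintf("parse error at line %d: unknown code %s", i, sQuote(bad[1L])))
    fields
  })
  ss_trajectory(do.call(rbind, rows), residue_labels = header)
}

#' @rdname read_ss_table
#' @param ss an [ss_trajectory()].
#' @export
write_ss_table <- function(ss, path) {
  stopifnot(inherits(ss, "ss_trajectory"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(ss$residue_labels, collapse = "\t"), con)
  writeLines(apply(ss$codes, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
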