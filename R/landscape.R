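#' Assemble a dynamic landscape
#'
#' Stacks the weight vectors of per-site multi-exponential fits (all on one
#' timescale grid) into a sites-by-timescales matrix: the "dynamic
#' landscape" of the molecule, in sequence order. Timescales zeroed by
#' [filter_artificial_slow()] stay zero.
#'
#' @param fits list of `expfit` objects sharing a grid.
#' @param labels site labels in sequence order; defaults to the fits' own.
#' @return An object of class `landscape` with fields `site_labels`, `taus`
#'   (ps), `weights` (matrix), `merged_k`.
#' @export
assemble_landscape <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 1L)
  for (f in fits) stopifnot(inherits(f, "expfit"))
  g <- fits[[1L]]$grid
  for (f in fits[-1L])
    if (!.same_grid(f$grid, g)) stop("fits do not share one timescale grid")
  if (is.null(labels)) labels <- vapply(fits, `[[`, character(1), "site_label")
  if (length(labels) != length(fits)) stop("one label per fit required")
  w <- do.call(rbind, lapply(fits, `[[`, "weights"))
  rownames(w) <- labels
  structure(list(site_labels = labels, taus = g$taus, weights = w,
                 merged_k = 1L),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d site(s) x %d timescale(s)%s\n",
              nrow(x$weights), ncol(x$weights),
              if (x$merged_k > 1L) sprintf(" (merged in groups of %d)", x$merged_k) else ""))
  invisible(x)
}

#' Merge consecutive landscape timescales
#'
#' Sums weights over groups of `k` consecutive grid timescales (a trailing
#' partial group is kept as its own bin) to emphasize the essential
#' timescale ranges in plots. Each merged bin is represented by the
#' geometric mean of its member timescales, preserving the log-symmetry of
#' the bin; per-site total weight is conserved exactly.
#'
#' @param ls a [assemble_landscape()] result.
#' @param k number of consecutive timescales per bin (>= 1).
#' @return A merged `landscape`.
#' @export
merge_consecutive <- function(ls, k = 5L) {
  stopifnot(inherits(ls, "landscape"))
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (k == 1L) return(ls)
  n <- length(ls$taus)
  bin <- (seq_len(n) - 1L) %/% k + 1L
  taus <- as.numeric(tapply(ls$taus, bin, function(z) exp(mean(log(z)))))
  w <- t(apply(ls$weights, 1L, function(row) tapply(row, bin, sum)))
  if (nrow(ls$weights) == 1L) w <- matrix(w, nrow = 1L)
  rownames(w) <- ls$site_labels
  structure(list(site_labels = ls$site_labels, taus = taus, weights = w,
                 merged_k = ls$merged_k * k),
            class = "landscape")
}

#' Dominant rotational timescale of a fit
#'
#' Merges the fit's weights in bins of `k` consecutive grid timescales,
#' picks the bin with the largest weight (ties broken towards the slowest
#' bin, so the result is deterministic), and reports the weighted geometric
#' mean timescale of that bin together with the total weight within
#' `window/2` decades on either side of it.
#'
#' @param fit an `expfit`.
#' @param window width of the weight-collection window in decades
#'   (default 0.5).
#' @param k merge width used to locate the dominant bin (default 5).
#' @return Named list `tau_ps`, `weight`.
#' @export
dominant_timescale <- function(fit, window = 0.5, k = 5L) {
  stopifnot(inherits(fit, "expfit"))
  w <- fit$weights
  if (all(w == 0)) stop("fit has all-zero weights")
  taus <- fit$grid$taus
  bin <- (seq_along(taus) - 1L) %/% as.integer(k) + 1L
  bw <- tapply(w, bin, sum)
  best <- max(which(bw == max(bw)))            # tie-break: slowest bin
  in_bin <- bin == best
  tau_star <- exp(sum(w[in_bin] * log(taus[in_bin])) / sum(w[in_bin]))
  near <- abs(log10(taus) - log10(tau_star)) <= window / 2
  list(tau_ps = tau_star, weight = sum(w[near]))
}

#' @export
plot.landscape <- function(x, max_cex = 3, ...) {
  nt <- length(x$taus); ns <- nrow(x$weights)
  xs <- rep(log10(x$taus), each = ns)
  ys <- rep(seq_len(ns), times = nt)
  w <- as.vector(x$weights)
  keep <- w > 0
  graphics::plot(xs[keep], ys[keep], cex = max_cex * sqrt(w[keep] / max(w)),
                 pch = 16, col = grDevices::adjustcolor(4, 0.6),
                 xlab = "log10 timescale (ps)", ylab = "site",
                 yaxt = "n", ...)
  graphics::axis(2, at = seq_len(ns), labels = x$site_labels, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Write / read a landscape table
#'
#' Long-format TSV (`site`, `tau_ps`, `weight`), suitable for bubble plots.
#'
#' @param ls a `landscape`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_landscape_table <- function(ls, path) {
  stopifnot(inherits(ls, "landscape"))
  df <- data.frame(site = rep(ls$site_labels, times = length(ls$taus)),
                   tau_ps = rep(ls$taus, each = nrow(ls$weights)),
                   weight = as.vector(ls$weights))
  df <- df[df$weight > 0, ]
  utils::write.table(format(df, digits = 9, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
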