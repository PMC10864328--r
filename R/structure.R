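#' Per-residue helicity propensity
#'
#' Fraction of frames each residue spends in a helical state. "Helical" is
#' the DSSP set {H, G, I} (alpha, 3-10, pi) by default; the set is
#' configurable because different conventions count only H.
#'
#' @param ss an [ss_trajectory()].
#' @param helix_codes DSSP codes counted as helix (default `c("H","G","I")`).
#' @return An object of class `helicity_profile`: data frame with columns
#'   `residue`, `helicity`, `local` (the latter `NA` until
#'   [local_environment_helicity()] fills it).
#' @export
helicity_propensity <- function(ss, helix_codes = c("H", "G", "I")) {
  stopifnot(inherits(ss, "ss_trajectory"))
  if (nrow(ss$codes) == 0L) stop("empty secondary-structure trajectory")
  bad <- setdiff(helix_codes, .dssp_alphabet)
  if (length(bad)) stop(sprintf("helix code(s) outside the DSSP alphabet: %s",
                                paste(sQuote(bad), collapse = ", ")))
  frac <- colMeans(matrix(ss$codes %in% helix_codes, nrow = nrow(ss$codes)))
  structure(data.frame(residue = ss$residue_labels, helicity = frac,
                       local = NA_real_, stringsAsFactors = FALSE),
            class = c("helicity_profile", "data.frame"))
}

#' Local-environment helicity
#'
#' For each residue, the average helicity over the residue and its left and
#' right neighbours where these exist: interior residues average 3 values,
#' terminal residues 2, and a single-residue profile is returned unchanged.
#' Note the operation is not idempotent for non-constant profiles - apply it
#' once.
#'
#' @param profile a [helicity_propensity()] result.
#' @return The profile with the `local` column filled.
#' @export
local_environment_helicity <- function(profile) {
  stopifnot(inherits(profile, "helicity_profile"))
  h <- profile$helicity
  n <- length(h)
  if (n == 0L) stop("empty profile")
  loc <- vapply(seq_len(n), function(i) {
    mean(h[max(1L, i - 1L):min(n, i + 1L)])
  }, numeric(1))
  profile$local <- loc
  profile
}

#' Pearson correlation with p-value
#'
#' Sample Pearson correlation coefficient and the two-sided p-value from the
#' t distribution with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return List with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlate helicity with relaxation observables
#'
#' Pearson r and p between local-environment helicity and each relaxation
#' observable, matching residues by position.
#'
#' @param profile a [local_environment_helicity()]-filled profile.
#' @param relax data frame with columns among `T1_s`, `T2_s`, `hetNOE`, one
#'   row per residue in the profile's order (e.g. from rbinding
#'   `as.data.frame(relaxation_result)` rows).
#' @return Data frame with columns `observable`, `r`, `p`.
#' @export
correlate_helicity <- function(profile, relax) {
  stopifnot(inherits(profile, "helicity_profile"))
  if (any(is.na(profile$local)))
    stop("run local_environment_helicity() on the profile first")
  if (nrow(relax) != nrow(profile))
    stop("one relaxation row per profile residue required")
  obs <- intersect(c("T1_s", "T2_s", "hetNOE"), names(relax))
  obs <- obs[vapply(obs, function(o) !all(is.na(relax[[o]])), logical(1))]
  if (!length(obs)) stop("no relaxation observables found")
  rows <- lapply(obs, function(o) {
    ok <- !is.na(relax[[o]])
    ct <- pearson_with_p(profile$local[ok], relax[[o]][ok])
    data.frame(observable = o, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
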