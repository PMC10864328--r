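#' Frame coordinates
#'
#' One trajectory frame for geometric analyses: atom positions (nm),
#' molecule ids partitioning the atoms, per-atom masses, and an optional
#' orthorhombic box.
#'
#' @param xyz `n x 3` numeric matrix of positions in nm.
#' @param mol_ids vector (length n) of molecule identifiers.
#' @param masses per-atom masses (default 1, i.e. geometric weighting).
#' @param box optional length-3 box edge lengths in nm.
#' @return An object of class `frame_coordinates`.
#' @export
frame_coordinates <- function(xyz, mol_ids, masses = rep(1, nrow(xyz)),
                              box = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || any(!is.finite(xyz))) stop("'xyz' must be finite n x 3")
  if (length(mol_ids) != nrow(xyz)) stop("one molecule id per atom required")
  if (length(masses) != nrow(xyz) || any(masses <= 0))
    stop("one positive mass per atom required")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(box <= 0)) stop("'box' must be 3 positive lengths")
  }
  structure(list(xyz = xyz, mol_ids = mol_ids, masses = as.numeric(masses),
                 box = box),
            class = "frame_coordinates")
}

#' Micelle membership by distance cutoff
#'
#' Returns the candidate molecules with at least one atom within
#' `cutoff_nm` (minimum-image distance if the frame has a box) of at least
#' one peptide atom. This is the per-frame definition of "in the micelle";
#' the cutoff (1.4-1.8 nm in practice, default 1.8) is set per system.
#'
#' @param frame a [frame_coordinates()].
#' @param peptide_ids molecule ids forming the peptide selection.
#' @param candidate_ids molecule ids to test for membership.
#' @param cutoff_nm distance cutoff in nm (default 1.8).
#' @return Vector of member molecule ids (subset of `candidate_ids`).
#' @export
micelle_members <- function(frame, peptide_ids, candidate_ids,
                            cutoff_nm = 1.8) {
  stopifnot(inherits(frame, "frame_coordinates"))
  if (cutoff_nm <= 0) stop("'cutoff_nm' must be positive")
  pep <- frame$xyz[frame$mol_ids %in% peptide_ids, , drop = FALSE]
  if (nrow(pep) == 0L) stop("empty peptide selection")
  members <- c()
  for (id in unique(candidate_ids)) {
    cand <- frame$xyz[frame$mol_ids == id, , drop = FALSE]
    if (nrow(cand) == 0L) next
    hit <- FALSE
    for (i in seq_len(nrow(cand))) {
      d <- sweep(pep, 2L, cand[i, ])
      if (!is.null(frame$box)) d <- minimum_image(d, frame$box)
      if (min(rowSums(d^2)) <= cutoff_nm^2) { hit <- TRUE; break }
    }
    if (hit) members <- c(members, id)
  }
  members
}

#' Mass-weighted radius of gyration
#'
#' Rg about the centre of mass of the selected molecules, in nm. For micelle
#' radii the convention is to select the member detergents together with the
#' peptide(s), compute Rg per frame, and time-average afterwards.
#'
#' @param frame a [frame_coordinates()].
#' @param ids molecule ids to include; `NULL` means all atoms.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, ids = NULL) {
  stopifnot(inherits(frame, "frame_coordinates"))
  sel <- if (is.null(ids)) rep(TRUE, nrow(frame$xyz)) else frame$mol_ids %in% ids
  if (!any(sel)) stop("empty selection")
  x <- frame$xyz[sel, , drop = FALSE]
  m <- frame$masses[sel]
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2L, com)^2)) / sum(m))
}

#' Per-frame micelle composition
#'
#' Applies [micelle_members()] and [radius_of_gyration()] (members plus
#' peptide) to every frame of a list of [frame_coordinates()].
#'
#' @inheritParams micelle_members
#' @param frames list of [frame_coordinates()].
#' @return An object of class `micelle_composition`: list with `members`
#'   (per-frame id vectors), `n_members`, `rg_nm` (per-frame), `cutoff_nm`.
#' @export
micelle_composition <- function(frames, peptide_ids, candidate_ids,
                                cutoff_nm = 1.8) {
  members <- lapply(frames, micelle_members, peptide_ids = peptide_ids,
                    candidate_ids = candidate_ids, cutoff_nm = cutoff_nm)
  rg <- mapply(function(fr, mem) radius_of_gyration(fr, c(peptide_ids, mem)),
               frames, members)
  structure(list(members = members,
                 n_members = lengths(members),
                 rg_nm = as.numeric(rg), cutoff_nm = cutoff_nm),
            class = "micelle_composition")
}

#' @export
print.micelle_composition <- function(x, ...) {
  cat(sprintf("<micelle_composition> %d frames, cutoff %.2f nm, <members> = %.1f, <Rg> = %.3f nm\n",
              length(x$members), x$cutoff_nm, mean(x$n_members), mean(x$rg_nm)))
  invisible(x)
}

# --- Stokes-Einstein --------------------------------------------------------

.se_factor <- function(convention) {
  # D_r = 1/(6 pi tau) convention: tau = 8 eta r^3 / (6 kB T).
  # Standard tau = 1/(6 D_r): an extra factor pi.
  switch(match.arg(convention, c("six_pi", "standard")),
         six_pi = 8 / 6, standard = 8 * pi / 6)
}

#' Stokes-Einstein rotational timescale and its inversions
#'
#' Rotational diffusion of a rigid sphere of radius `r` in a medium of
#' viscosity `eta`: D_r = kB T / (8 pi eta r^3). The default timescale
#' convention is D_r = 1/(6 pi tau), giving tau = 8 eta r^3 / (6 kB T);
#' `convention = "standard"` uses the textbook tau = 1/(6 D_r) instead
#' (a factor pi longer). `invert_radius()` and `invert_viscosity()` solve
#' the same identity for r or eta.
#'
#' @param r_nm sphere radius in nm.
#' @param T_K temperature in K.
#' @param eta_mPas viscosity in mPa s.
#' @param convention `"six_pi"` (default) or `"standard"`.
#' @return `stokes_einstein_timescale()`: tau in ns;
#'   `invert_radius()`: r in nm; `invert_viscosity()`: eta in mPa s.
#' @export
stokes_einstein_timescale <- function(r_nm, T_K, eta_mPas,
                                      convention = "six_pi") {
  if (any(c(r_nm, T_K, eta_mPas) <= 0)) stop("all arguments must be positive")
  tau_s <- .se_factor(convention) * (eta_mPas * 1e-3) * (r_nm * 1e-9)^3 /
    (.kB * T_K)
  tau_s * 1e9
}

#' @rdname stokes_einstein_timescale
#' @param tau_ns rotational timescale in ns.
#' @export
invert_radius <- function(tau_ns, T_K, eta_mPas, convention = "six_pi") {
  if (any(c(tau_ns, T_K, eta_mPas) <= 0)) stop("all arguments must be positive")
  r3 <- (tau_ns * 1e-9) * .kB * T_K / (.se_factor(convention) * eta_mPas * 1e-3)
  r3^(1 / 3) * 1e9
}

#' @rdname stokes_einstein_timescale
#' @export
invert_viscosity <- function(tau_ns, T_K, r_nm, convention = "six_pi") {
  if (any(c(tau_ns, T_K, r_nm) <= 0)) stop("all arguments must be positive")
  eta <- (tau_ns * 1e-9) * .kB * T_K / (.se_factor(convention) * (r_nm * 1e-9)^3)
  eta * 1e3
}

# --- principal axes and superposition ---------------------------------------

.principal_axis <- function(coords, masses = rep(1, nrow(coords))) {
  if (nrow(coords) < 3L) stop("need at least 3 atoms")
  x <- sweep(coords, 2L, colSums(coords * masses) / sum(masses))
  sv <- svd(x * sqrt(masses))
  if (sv$d[2L] < 1e-9 * sv$d[1L])
    stop("degenerate (collinear) selection: principal axis undefined")
  # dominant (long) axis = direction of largest positional variance,
  # i.e. smallest moment of inertia
  sv$v[, 1L]
}

#' Angle between the dominant principal axes of two selections
#'
#' Long-axis angle between two atom selections (e.g. two peptides in one
#' micelle), folded into \[0, 90\] degrees because principal axes have no
#' sign.
#'
#' @param coordsA,coordsB `n x 3` coordinate matrices (>= 3 non-collinear
#'   atoms each).
#' @param massesA,massesB optional per-atom masses.
#' @return Angle in degrees in \[0, 90\].
#' @export
principal_axis_angle <- function(coordsA, coordsB,
                                 massesA = rep(1, nrow(coordsA)),
                                 massesB = rep(1, nrow(coordsB))) {
  a <- .principal_axis(as.matrix(coordsA), massesA)
  b <- .principal_axis(as.matrix(coordsB), massesB)
  cosang <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, cosang)) * 180 / pi
}

#' Remove rigid-body rotation from a trajectory
#'
#' Least-squares superposes every frame onto the first frame using a
#' reference selection: rotation only (proper rotation enforced, no
#' reflection), taken about the centres of mass. The returned frames see the
#' remaining motion in the reference's own frame, so e.g. detergent
#' correlation functions computed afterwards report motion relative to the
#' (rigid) peptide. Meaningful only when the reference is rigid enough for
#' superposition.
#'
#' @param frames list of `n x 3` coordinate matrices (all with equal atom
#'   count), or a single `n_frames x 3N` matrix.
#' @param reference_idx integer indices of the reference atoms.
#' @return List of transformed coordinate matrices.
#' @export
remove_rotation <- function(frames, reference_idx) {
  if (is.matrix(frames))
    frames <- lapply(seq_len(nrow(frames)), function(i)
      matrix(frames[i, ], ncol = 3L, byrow = TRUE))
  ref <- frames[[1L]][reference_idx, , drop = FALSE]
  if (nrow(ref) < 3L) stop("reference selection needs at least 3 atoms")
  ref_com <- colMeans(ref)
  ref_c <- sweep(ref, 2L, ref_com)
  if (svd(ref_c)$d[2L] < 1e-9 * max(svd(ref_c)$d))
    stop("degenerate reference selection")
  lapply(frames, function(fr) {
    mob <- fr[reference_idx, , drop = FALSE]
    com <- colMeans(mob)
    R <- .kabsch(sweep(mob, 2L, com), ref_c)
    sweep(sweep(fr, 2L, com) %*% R, 2L, ref_com, `+`)
  })
}

# Optimal proper rotation aligning centred coordinates A onto B.
.kabsch <- function(A, B) {
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}
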