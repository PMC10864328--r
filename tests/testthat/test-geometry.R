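toy_frame <- function() {
  # peptide (mol 0) at origin; 5 single-atom candidates at hand-placed distances
  xyz <- rbind(c(0, 0, 0),
               c(0.5, 0, 0), c(0, 1.3, 0), c(0, 0, 1.7),
               c(1.9, 0, 0), c(0, 3.0, 0))
  frame_coordinates(xyz, mol_ids = 0:5)
}

test_that("micelle membership follows the distance cutoff", {
  fr <- toy_frame()
  expect_equal(micelle_members(fr, 0, 1:5, cutoff_nm = 1.8), 1:3)
  expect_equal(micelle_members(fr, 0, 4, cutoff_nm = 1.8), NULL)
  expect_equal(micelle_members(fr, 0, 2, cutoff_nm = 1.8), 2)
  expect_error(micelle_members(fr, 99, 1:5), "empty peptide")
})

test_that("membership is monotone in the cutoff", {
  set.seed(43)
  xyz <- rbind(matrix(rnorm(30, sd = 0.3), 10, 3),
               matrix(rnorm(60, sd = 2.0), 20, 3))
  fr <- frame_coordinates(xyz, mol_ids = c(rep(0, 10), rep(1:10, each = 2)))
  cuts <- c(0.5, 1.0, 1.5, 2.0, 3.0)
  prev <- c()
  for (ct in cuts) {
    cur <- micelle_members(fr, 0, 1:10, cutoff_nm = ct)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("membership uses minimum-image distances when a box is present", {
  xyz <- rbind(c(0.1, 0, 0), c(9.8, 0, 0))
  fr <- frame_coordinates(xyz, mol_ids = c(0, 1), box = c(10, 10, 10))
  expect_equal(micelle_members(fr, 0, 1, cutoff_nm = 0.5), 1)  # 0.3 nm across the edge
  fr2 <- frame_coordinates(xyz, mol_ids = c(0, 1))
  expect_null(micelle_members(fr2, 0, 1, cutoff_nm = 0.5))
})

test_that("radius of gyration matches closed forms and is rigid-motion invariant", {
  two <- frame_coordinates(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1))
  expect_equal(radius_of_gyration(two), 1)

  same <- frame_coordinates(matrix(1.5, 4, 3), rep(1, 4))
  expect_equal(radius_of_gyration(same), 0)

  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  frc <- frame_coordinates(cube, rep(1, 8))
  expect_equal(radius_of_gyration(frc), sqrt(3) / 2, tolerance = 1e-12)

  R <- rotation_matrix(c(0.3, 1, -2), 0.9)
  moved <- frame_coordinates(sweep(cube %*% t(R), 2, c(5, -2, 1), `+`), rep(1, 8))
  expect_equal(radius_of_gyration(moved), sqrt(3) / 2, tolerance = 1e-12)

  expect_error(radius_of_gyration(frc, ids = 99), "empty")
})

test_that("micelle composition averages members-plus-peptide Rg per frame", {
  frames <- list(toy_frame(), toy_frame())
  comp <- micelle_composition(frames, 0, 1:5, cutoff_nm = 1.8)
  expect_equal(comp$n_members, c(3L, 3L))
  manual <- radius_of_gyration(frames[[1]], c(0, 1, 2, 3))
  expect_equal(comp$rg_nm, rep(manual, 2), tolerance = 1e-12)
})

test_that("Stokes-Einstein inversion reproduces the 3.0 nm micelle radius", {
  r <- invert_radius(tau_ns = 6, T_K = 310, eta_mPas = 0.69)
  expect_equal(round(r, 1), 3.0)
  # exact algebraic round trip
  for (rr in c(0.8, 1.6, 3.0)) {
    tau <- stokes_einstein_timescale(rr, 310, 0.69)
    expect_equal(invert_radius(tau, 310, 0.69), rr, tolerance = 1e-12)
    expect_equal(invert_viscosity(tau, 310, rr), 0.69, tolerance = 1e-12)
  }
  # cubic law
  expect_equal(stokes_einstein_timescale(2, 310, 0.69) /
                 stokes_einstein_timescale(1, 310, 0.69), 8, tolerance = 1e-12)
  # the standard tau = 1/(6 D_r) convention is a factor pi slower
  expect_equal(stokes_einstein_timescale(1, 310, 0.69, convention = "standard") /
                 stokes_einstein_timescale(1, 310, 0.69), pi, tolerance = 1e-12)
  expect_error(stokes_einstein_timescale(-1, 310, 0.69), "positive")
})

test_that("principal-axis angles fold into [0, 90] degrees", {
  rod <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    outer(seq(-1, 1, length.out = 7), dir) + matrix(rnorm(21, sd = 1e-3), 7, 3)
  }
  set.seed(47)
  expect_equal(principal_axis_angle(rod(c(0, 0, 1)), rod(c(0, 0, 1))), 0,
               tolerance = 0.5)
  expect_equal(principal_axis_angle(rod(c(0, 0, 1)), rod(c(1, 0, 0))), 90,
               tolerance = 0.5)
  expect_equal(principal_axis_angle(rod(c(0, 0, 1)), rod(c(1, 0, 1))), 45,
               tolerance = 0.5)
  collinear <- outer(1:5, c(0, 0, 1))
  expect_error(principal_axis_angle(collinear, rod(c(1, 0, 0))), "collinear")
})

test_that("rotation removal undoes a pure rigid rotation exactly", {
  set.seed(53)
  base <- matrix(rnorm(45), 15, 3)
  frames <- lapply(seq(0, 1.5, length.out = 6), function(a)
    base %*% t(rotation_matrix(c(1, 2, 3), a)))
  fixed <- remove_rotation(frames, reference_idx = 1:15)
  for (f in fixed) expect_lt(max(abs(f - base)), 1e-6)

  ident <- remove_rotation(rep(list(base), 3), reference_idx = 1:15)
  for (f in ident) expect_equal(f, base, tolerance = 1e-9)
})

test_that("rotation removal reaches the noise floor and preserves distances", {
  set.seed(59)
  base <- matrix(rnorm(60), 20, 3)
  sigma <- 0.01
  frames <- lapply(seq(0.2, 1.2, length.out = 5), function(a)
    (base + matrix(rnorm(60, sd = sigma), 20, 3)) %*% t(rotation_matrix(c(1, 0, 1), a)))
  fixed <- remove_rotation(c(list(base), frames), reference_idx = 1:20)
  for (f in fixed[-1]) {
    rmsd <- sqrt(mean(rowSums((f - base)^2)))
    expect_lte(rmsd, 2 * sigma * sqrt(3))
  }
  # rigid transform only: intra-selection distances unchanged
  d_before <- as.matrix(dist(frames[[2]]))
  d_after <- as.matrix(dist(fixed[[3]]))
  expect_equal(d_before, d_after, tolerance = 1e-9)
  expect_error(remove_rotation(frames, reference_idx = 1:2), "3 atoms")
})
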