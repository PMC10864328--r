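make_vt <- function(n_frames = 10, n_sites = 2, dt = 1, seed = 1) {
  set.seed(seed)
  vecs <- lapply(seq_len(n_sites), function(i) random_unit_vectors(n_frames))
  names(vecs) <- paste0("A", seq_len(n_sites), ":N-H")
  vector_trajectory(dt * (seq_len(n_frames) - 1), vecs)
}

test_that("vector trajectory enforces unit norms and uniform spacing", {
  v <- matrix(c(0, 0, 1), 3, 3, byrow = TRUE)
  expect_error(vector_trajectory(c(0, 1, 2.5), list(a = v)), "uniform")
  expect_error(vector_trajectory(c(0, 1, 2), list(a = 2 * v)), "norm")
  bad <- v; bad[2, ] <- c(0, 0, 1.00001)
  expect_error(vector_trajectory(0:2, list(a = bad)), "non-unit")
  expect_silent(vector_trajectory(0:2, list(a = bad), normalize = TRUE))
  short <- v[1:2, ]
  expect_error(vector_trajectory(0:2, list(a = v, b = short)), "frames")
})

test_that("vector table round-trips within 1e-9", {
  vt <- make_vt(10, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vector_table(vt, path)
  back <- read_vector_table(path)
  expect_identical(back$site_labels, vt$site_labels)
  expect_equal(back$times, vt$times, tolerance = 1e-9)
  for (s in vt$site_labels)
    expect_lt(max(abs(back$vectors[[s]] - vt$vectors[[s]])), 1e-9)
})

test_that("vector table norm policy: renormalize small deviations, reject large", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# site a", "time_ps\tx\ty\tz",
               "0\t0\t0\t1", "1\t0\t0\t0.995"), path)
  expect_warning(vt <- read_vector_table(path), "re-normaliz")
  expect_equal(unname(vt$vectors$a[2, 3]), 1, tolerance = 1e-12)
  # a deviation below the 1e-3 warning threshold is renormalized silently
  writeLines(c("# site a", "time_ps\tx\ty\tz",
               "0\t0\t0\t1", "1\t0\t0\t0.9995"), path)
  expect_silent(vt2 <- read_vector_table(path))
  expect_equal(unname(vt2$vectors$a[2, 3]), 1, tolerance = 1e-12)
  writeLines(c("# site a", "time_ps\tx\ty\tz",
               "0\t0\t0\t1", "1\t0\t0\t0.5"), path)
  expect_error(read_vector_table(path), "0.1")
})

test_that("malformed vector tables report the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# site a", "time_ps\tx\ty\tz",
               "0\t0\t0\t1", "1\t0\tnope\t1"), path)
  expect_error(read_vector_table(path), "line 4")
  writeLines(c("0\t0\t0\t1"), path)
  expect_error(read_vector_table(path), "site")
})

test_that("secondary-structure tables read, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tr2\tr3", "H\tH\tH", "H\tH\tH"), path)
  ss <- read_ss_table(path)
  expect_equal(dim(ss$codes), c(2L, 3L))
  expect_true(all(ss$codes == "H"))

  writeLines(c("r1\tr2", "H\tX"), path)
  expect_error(read_ss_table(path), "'X'")
  writeLines(c("r1\tr2", "H\tE\tT"), path)
  expect_error(read_ss_table(path), "ragged")

  codes <- matrix(c("H", "E", "~", "T", "G", "B", "S", "I"), 4, 2)
  ss2 <- ss_trajectory(codes, c("A1", "A2"))
  write_ss_table(ss2, path)
  back <- read_ss_table(path)
  expect_identical(unname(back$codes), unname(ss2$codes))
})

pdb_frame <- function(coords) {
  # coords: matrix with rows N, H (Angstrom)
  sprintf("ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          seq_len(nrow(coords)), c(" N", " H"), 1,
          coords[, 1], coords[, 2], coords[, 3], c("N", "H"))
}

write_multimodel_pdb <- function(path, frames, box = c(30, 30, 30)) {
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                   box[1], box[2], box[3])
  for (i in seq_along(frames)) {
    lines <- c(lines, sprintf("MODEL %8d", i), pdb_frame(frames[[i]]), "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
}

test_that("bond-vector extraction normalizes fixed displacements", {
  path <- withr::local_tempfile(fileext = ".pdb")
  fr <- matrix(c(0, 0, 0, 0, 0, 1.02), 2, 3, byrow = TRUE)
  write_multimodel_pdb(path, rep(list(fr), 5))
  vt <- extract_bond_vectors(path, pairs = data.frame(label = "A1:N-H", resno = 1))
  expect_equal(vt$n_frames, 5L)
  expect_equal(unname(vt$vectors[[1]]),
               matrix(rep(c(0, 0, 1), each = 5), 5, 3), tolerance = 1e-9)
})

test_that("extraction applies the minimum-image convention across the box edge", {
  path <- withr::local_tempfile(fileext = ".pdb")
  # N at x = 0.1 A, H at x = L - 0.1 A: true bond points in -x
  fr <- matrix(c(0.1, 0, 0, 29.9, 0, 0), 2, 3, byrow = TRUE)
  write_multimodel_pdb(path, list(fr, fr), box = c(30, 30, 30))
  vt <- extract_bond_vectors(path, pairs = data.frame(label = "A1:N-H", resno = 1))
  expect_equal(unname(vt$vectors[[1]][1, ]), c(-1, 0, 0), tolerance = 1e-9)
})

test_that("extraction is invariant under rigid translation", {
  path1 <- withr::local_tempfile(fileext = ".pdb")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  set.seed(3)
  frames <- lapply(1:4, function(i) {
    n <- c(5, 5, 5) + rnorm(3, sd = 0.1)
    rbind(n, n + random_unit_vectors(1) * 1.02)
  })
  write_multimodel_pdb(path1, frames)
  write_multimodel_pdb(path2, lapply(frames, function(f) sweep(f, 2, c(3.2, -1.1, 7.9), `+`)))
  p <- data.frame(label = "A1:N-H", resno = 1)
  v1 <- extract_bond_vectors(path1, pairs = p)
  v2 <- extract_bond_vectors(path2, pairs = p)
  expect_equal(v1$vectors[[1]], v2$vectors[[1]], tolerance = 1e-9)
})

test_that("unresolvable selections name the missing atom", {
  path <- withr::local_tempfile(fileext = ".pdb")
  fr <- matrix(c(0, 0, 0, 0, 0, 1.02), 2, 3, byrow = TRUE)
  write_multimodel_pdb(path, list(fr))
  expect_error(
    extract_bond_vectors(path, pairs = data.frame(label = "x", resno = 2)),
    "residue 2")
  expect_error(
    extract_bond_vectors(path, pairs = data.frame(label = "x", resno = 1,
                                                  atom_light = "HD2")),
    "HD2")
})

test_that("generator output survives a write/read round trip", {
  vt <- simulate_isotropic_rotor(D_r = 1, dt = 1, n_steps = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vector_table(vt, path)
  back <- read_vector_table(path)
  expect_lt(max(abs(back$vectors[[1]] - vt$vectors[[1]])), 1e-6)
})
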