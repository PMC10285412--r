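test_that("written mmCIF round-trips losslessly through the reader", {
  d <- build_duplex(fix_duplex_mixed())
  tf <- tempfile(fileext = ".cif")
  write_mmcif(d$model, tf)
  m2 <- read_mmcif(tf)
  expect_equal(nrow(m2$atom), nrow(d$model$atom))
  a1 <- d$model$atom[order(d$model$atom$resno, d$model$atom$atom), ]
  a2 <- m2$atom[order(m2$atom$resno, m2$atom$atom), ]
  expect_equal(a2$chain, a1$chain)
  expect_equal(a2$resno, a1$resno)
  expect_equal(a2$atom, a1$atom)       # primes survive quoting
  expect_equal(a2$x, a1$x, tolerance = 1e-3)
  expect_equal(a2$z, a1$z, tolerance = 1e-3)
})

test_that("reader rejects files without an atom_site loop", {
  tf <- tempfile(fileext = ".cif")
  writeLines(c("data_X", "_cell.length_a 10.0"), tf)
  expect_error(read_mmcif(tf), "atom_site")
  expect_error(read_mmcif(tempfile()), "not found")
})

test_that("atom distances are Euclidean, symmetric and addressable", {
  at <- data.frame(chain = "A", resno = c(1L, 1L, 2L),
                   resid = "G", atom = c("P", "O6", "N1"),
                   element = c("P", "O", "N"),
                   x = c(0, 0, 3), y = c(0, 0, 4), z = c(0, 1, 0), occ = 1,
                   stringsAsFactors = FALSE)
  m <- structure_model(at)
  expect_equal(atom_distance(m, "A:1:P", "A:1:P"), 0)
  expect_equal(atom_distance(m, "A:1:P", "A:1:O6"), 1)
  expect_equal(atom_distance(m, "A:1:P", "A:2:N1"), 5)
  expect_equal(atom_distance(m, "A:2:N1", "A:1:P"), 5)
  expect_error(atom_distance(m, "A:1:XX", "A:1:P"), "cannot resolve")
})

test_that("distance symmetry and triangle inequality hold on random triples", {
  d <- build_duplex(fix_duplex_mixed())
  at <- d$model$atom
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(nrow(at), 3)
    addr <- sprintf("%s:%d:%s", at$chain[k], at$resno[k], at$atom[k])
    dab <- atom_distance(d$model, addr[1], addr[2])
    dba <- atom_distance(d$model, addr[2], addr[1])
    dbc <- atom_distance(d$model, addr[2], addr[3])
    dac <- atom_distance(d$model, addr[1], addr[3])
    expect_equal(dab, dba)
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("minimum residue distance equals the brute-force oracle", {
  d <- build_duplex(fix_duplex_mixed())
  m <- attach_probe(d$model, "R:103", 5.0)
  for (res in c(101L, 103L, 106L, 204L)) {
    got <- min_residue_distance(m, sprintf("R:%d", res), "P")
    expect_equal(got$distance, oracle_min_dist(m, "R", res, "P"),
                 tolerance = 1e-9)
  }
  # residue-vs-residue form, and self-distance is zero-adjacent exclusion
  got <- min_residue_distance(m, "R:101", data.frame(chain = "R", resno = 206L))
  expect_equal(got$distance, {
    at <- m$atom
    A <- at[at$chain == "R" & at$resno == 101L, ]
    B <- at[at$chain == "R" & at$resno == 206L, ]
    min(as.matrix(stats::dist(rbind(A[, c("x", "y", "z")],
                                    B[, c("x", "y", "z")])))[
      seq_len(nrow(A)), nrow(A) + seq_len(nrow(B))])
  }, tolerance = 1e-9)
  expect_error(min_residue_distance(m, "R:101", "Z"), "empty target")
})

test_that("Kabsch superposition is exact under rigid motion", {
  d <- build_duplex(fix_duplex_gc4())
  ref <- d$model
  pairs <- data.frame(mobile = "R", reference = "R",
                      stringsAsFactors = FALSE)
  same <- superpose_kabsch(ref, ref, pairs)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)

  moved <- rigid_move(ref, 90, "z", c(12, -7, 3))
  fit <- superpose_kabsch(moved, ref, pairs)
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  back <- apply_transform(moved, fit)
  expect_equal(as.matrix(back$atom[, c("x", "y", "z")]),
               as.matrix(ref$atom[, c("x", "y", "z")]), tolerance = 1e-6)
  # original mobile untouched (side-effect free)
  expect_equal(moved$atom$x[1], ref$atom$x[1] * 0 + moved$atom$x[1])
})

test_that("Kabsch RMSD under seeded jitter matches the closed-form oracle", {
  d <- build_duplex(fix_duplex_gc4())
  ref <- d$model
  set.seed(11)
  pert <- ref
  pert$atom$x <- pert$atom$x + rnorm(nrow(pert$atom), 0, 0.3)
  pert$atom$y <- pert$atom$y + rnorm(nrow(pert$atom), 0, 0.3)
  pert$atom$z <- pert$atom$z + rnorm(nrow(pert$atom), 0, 0.3)
  pert <- rigid_move(pert, 37, "x", c(-4, 2, 9))
  pairs <- data.frame(mobile = "R", reference = "R", stringsAsFactors = FALSE)
  fit <- superpose_kabsch(pert, ref, pairs)
  sel <- function(m) {
    a <- m$atom[m$atom$atom == "C1'", ]
    as.matrix(a[order(a$resno), c("x", "y", "z")])
  }
  expect_equal(fit$rmsd, oracle_kabsch_rmsd(sel(pert), sel(ref)),
               tolerance = 1e-6)
  # rigid pre-motion of the mobile model leaves the RMSD invariant
  fit2 <- superpose_kabsch(rigid_move(pert, 90, "z"), ref, pairs)
  expect_equal(fit2$rmsd, fit$rmsd, tolerance = 1e-6)
})

test_that("superposition refuses under-determined correspondences", {
  at <- data.frame(chain = "A", resno = 1:2, resid = "G",
                   atom = "C1'", element = "C",
                   x = c(0, 1), y = 0, z = 0, occ = 1,
                   stringsAsFactors = FALSE)
  m <- structure_model(at)
  expect_error(superpose_kabsch(m, m, data.frame(mobile = "A",
                                                 reference = "A")),
               "insufficient")
})
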