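sym_ninj1 <- screw_symmetry(rise = 20.95, twist = -1.05)

test_that("a single-subunit filament is coordinate-identical to the protomer", {
  p <- synth_protomer(seed = 1)
  fil <- build_filament(p, sym_ninj1, n = 1)
  expect_equal(as.matrix(fil[, c("x", "y", "z")]),
               as.matrix(p[, c("x", "y", "z")]), tolerance = 1e-12)
  expect_identical(assembly_topology(fil), "linear")
})

test_that("consecutive subunits are displaced by the rise along the axis", {
  p <- synth_protomer(seed = 2)
  fil <- build_filament(p, sym_ninj1, n = 2)
  cents <- lapply(subunit_chains(fil), function(ch) {
    colMeans(as.matrix(fil[fil$chain == ch, c("x", "y", "z")]))
  })
  proj <- sum((cents[[2]] - cents[[1]]) * sym_ninj1$axis_direction)
  expect_equal(proj, 20.95, tolerance = 1e-9)
})

test_that("a 45-mer spans 44 steps of rise and twist", {
  p <- synth_protomer(seed = 3)
  fil <- build_filament(p, sym_ninj1, n = 45)
  chains <- subunit_chains(fil)
  first <- as.matrix(fil[fil$chain == chains[1], c("x", "y", "z")])
  last <- as.matrix(fil[fil$chain == chains[45], c("x", "y", "z")])
  kf <- ninjfil:::kabsch_fit(first, last)
  dec <- ninjfil:::screw_decompose(kf$R, kf$t)
  # 44 inter-subunit steps: axial span 44 x 20.95 = 921.8 A
  expect_equal(dec$rise, 44 * 20.95, tolerance = 1e-6)
  expect_equal(ninjfil:::rad2deg(dec$angle), 44 * -1.05, tolerance = 1e-6)
  # one further application of the screw operator completes 45 steps,
  # a cumulative rotation of -47.25 degrees
  expect_equal(45 * sym_ninj1$twist, -47.25)
})

test_that("non-finite protomer coordinates are rejected naming the atom", {
  p <- synth_protomer(seed = 1)
  p$x[5] <- NaN
  expect_error(build_filament(p, sym_ninj1, 3), p$atom[5])
})

test_that("estimate_screw recovers the generating parameters to 1e-6", {
  p <- synth_protomer(seed = 4)
  fit <- estimate_screw(build_filament(p, sym_ninj1, 20))
  expect_equal(fit$rise, 20.95, tolerance = 1e-6)
  expect_equal(fit$twist, -1.05, tolerance = 1e-6)
  expect_lt(fit$rmsd, 1e-8)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 19)
})

test_that("screw round trip holds over random rise/twist/n (property)", {
  set.seed(42)
  p <- synth_protomer(seed = 5)
  for (rep in 1:8) {
    rise <- runif(1, 1, 100)
    twist <- runif(1, -179, 179)
    if (abs(twist) < 1) twist <- twist + sign(twist + 0.5) * 2
    n <- sample(2:50, 1)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    sym <- screw_symmetry(rise, twist, axis, rnorm(3, sd = 10))
    fit <- estimate_screw(build_filament(p, sym, n))
    expect_equal(fit$rise, rise, tolerance = 1e-6)
    expect_equal(fit$twist, twist, tolerance = 1e-6)
  }
})

test_that("a pure translation estimates as rise with zero twist", {
  ca <- matrix(rnorm(30, sd = 5), 10, 3)
  p <- toy_protomer(1:10, rep("ALA", 10), ca)
  fil <- build_filament(p, screw_symmetry(7, 0, c(0, 0, 1)), 2)
  fit <- estimate_screw(fil)
  expect_equal(fit$rise, 7, tolerance = 1e-9)
  expect_equal(fit$twist, 0, tolerance = 1e-9)
})

test_that("assembly construction commutes with global rigid motions", {
  set.seed(7)
  p <- synth_protomer(seed = 6)
  rig <- random_rigid()
  sym <- screw_symmetry(15, 23, c(0, 0, 1), c(1, 2, 3))
  direct <- transform_atoms(build_filament(p, sym, 8), rig)
  moved <- build_filament(transform_atoms(p, rig), transform_sym(sym, rig), 8)
  expect_lt(max(abs(as.matrix(direct[, c("x", "y", "z")]) -
                    as.matrix(moved[, c("x", "y", "z")]))), 1e-9)
})

test_that("all subunits of one assembly are rigid copies (zero RMSD)", {
  p <- synth_protomer(seed = 8)
  fil <- build_filament(p, sym_ninj1, 5)
  subs <- ninjfil:::subunit_xyz(fil)
  for (i in 2:5) {
    expect_lt(superposed_rmsd(subs[[1]], subs[[i]]), 1e-9)
  }
})

test_that("ring closure places 45 subunits on a 150 A circle", {
  p <- synth_protomer(seed = 9)
  ring <- close_ring(p, sym_ninj1, 45)
  expect_identical(assembly_topology(ring), "ring")
  R <- attr(ring, "ring_radius")
  expect_equal(R, 45 * 20.95 / (2 * pi), tolerance = 1e-12)
  expect_equal(R, 150.0, tolerance = 1e-3)
  chains <- subunit_chains(ring)
  cents <- t(vapply(chains, function(ch) {
    colMeans(as.matrix(ring[ring$chain == ch, c("x", "y", "z")]))
  }, numeric(3)))
  # coplanar and equidistant from the ring centre
  expect_lt(diff(range(cents[, 3])), 1e-6)
  radii <- unname(sqrt(cents[, 1]^2 + cents[, 2]^2))
  expect_equal(radii, rep(R, 45), tolerance = 1e-9)
  # consecutive centroid chord = 2 R sin(pi/n) ~ 20.93 A
  chord <- unname(sqrt(rowSums((cents[-1, ] - cents[-45, ])^2)))
  expect_equal(chord, rep(2 * R * sin(pi / 45), 44), tolerance = 1e-9)
  expect_equal(2 * R * sin(pi / 45), 20.93, tolerance = 1e-2)
})

test_that("the ring placement map closes after n applications", {
  p <- synth_protomer(seed = 10)
  n <- 12
  ring <- close_ring(p, sym_ninj1, n)
  subs <- ninjfil:::subunit_xyz(ring)
  # subunit 0 -> 1 map, applied n times, returns subunit 0's pose
  kf <- ninjfil:::kabsch_fit(subs[[1]], subs[[2]])
  X <- subs[[1]]
  for (k in seq_len(n)) X <- sweep(X %*% t(kf$R), 2, kf$t, `+`)
  expect_lt(max(abs(X - subs[[1]])), 1e-6)
})

test_that("ring closure requires n >= 3", {
  p <- synth_protomer(seed = 1)
  expect_error(close_ring(p, sym_ninj1, 2), "n >= 3")
})

test_that("double filament is antiparallel and preserves internal geometry", {
  p <- synth_protomer(seed = 11)
  fil <- build_filament(p, sym_ninj1, 6)
  dbl <- stack_double_filament(fil, separation = 40)
  expect_identical(assembly_topology(dbl), "double_filament")
  axes <- attr(dbl, "filament_axes")
  expect_equal(sum(axes[1, ] * axes[2, ]), -1, tolerance = 1e-9)
  chains <- subunit_chains(dbl)
  half1 <- ninjfil:::new_assembly(dbl[dbl$chain %in% chains[1:6], ],
                                  "linear", NULL, chains[1:6])
  half2 <- ninjfil:::new_assembly(dbl[dbl$chain %in% chains[7:12], ],
                                  "linear", NULL, chains[7:12])
  f1 <- estimate_screw(half1); f2 <- estimate_screw(half2)
  expect_equal(f1$rise, f2$rise, tolerance = 1e-9)
  expect_equal(f1$twist, f2$twist, tolerance = 1e-9)
})

test_that("stacking clashes are detected and name the worst pair", {
  p <- synth_protomer(seed = 11)
  fil <- build_filament(p, sym_ninj1, 3)
  expect_error(stack_double_filament(fil, separation = 0), "clash")
})

test_that("the stacking interface is enriched in hydrophobic residues", {
  # protomer with a known hydrophobic face: Leu CB at azimuth 90, Lys at 270
  n_res <- 20
  z <- seq(0, 38, length.out = n_res)
  hydro <- rep(c(TRUE, FALSE), each = n_res / 2)
  az <- ifelse(hydro, pi / 2, 3 * pi / 2)
  ca <- cbind(3 * cos(az), 3 * sin(az), z)
  cb <- cbind(5 * cos(az), 5 * sin(az), z)
  p <- toy_protomer(1:n_res, ifelse(hydro, "LEU", "LYS"), ca, cb)
  fil <- build_filament(p, screw_symmetry(40, 0), 4)
  dbl <- stack_double_filament(fil, separation = 14)
  chains <- subunit_chains(dbl)
  first <- as.matrix(dbl[dbl$chain %in% chains[1:4], c("x", "y", "z")])
  second <- as.matrix(dbl[dbl$chain %in% chains[5:8], c("x", "y", "z")])
  sub1 <- dbl[dbl$chain %in% chains[1:4], ]
  mind <- vapply(seq_len(nrow(first)), function(i) {
    sqrt(min(colSums((t(second) - first[i, ])^2)))
  }, numeric(1))
  kd <- hydrophobicity_scale("kd")$values
  iface <- mind < 5
  expect_true(any(iface))
  expect_gt(mean(kd[sub1$resid[iface]]), mean(kd[sub1$resid[!iface]]))
})

test_that("mass photometry stoichiometry follows the mass ratio", {
  res <- subunit_count_from_mass(1.3e6, 1.6e4)
  expect_equal(res$ratio, 81.25)
  expect_identical(res$n_subunits, 81L)
  expect_equal(subunit_count_from_mass(5e4, 5e4)$ratio, 1)
  expect_error(subunit_count_from_mass(0, 1.6e4), "positive")
})
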