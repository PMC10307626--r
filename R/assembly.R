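#' Screw (helical) symmetry of a filament
#'
#' The screw operator relating consecutive subunits of a helical polymer:
#' a rotation of `twist` degrees about the filament axis followed by a
#' translation of `rise` Angstrom along it. The refined symmetry of the
#' NINJ1 filament is a rise of 20.95 Angstrom per subunit with a twist of
#' -1.05 degrees. The axis direction is oriented so that the rise is
#' positive; the twist sign then follows the right-hand rule.
#'
#' @param rise Translation per subunit along the axis (Angstrom, > 0).
#' @param twist Signed rotation per subunit (degrees).
#' @param axis_direction Unit 3-vector along the filament axis.
#' @param axis_point A point on the axis (Angstrom).
#'
#' @return An object of class `screw_symmetry`.
#' @export
#' @examples
#' screw_symmetry(rise = 20.95, twist = -1.05)
screw_symmetry <- function(rise, twist, axis_direction = c(0, 0, 1),
                           axis_point = c(0, 0, 0)) {
  if (!is.finite(rise) || rise <= 0) stop("rise must be > 0", call. = FALSE)
  n <- sqrt(sum(axis_direction^2))
  if (abs(n - 1) > 1e-9) {
    if (n < .Machine$double.eps) stop("axis_direction must be non-zero", call. = FALSE)
    axis_direction <- axis_direction / n
  }
  structure(list(rise = rise, twist = twist,
                 axis_direction = as.numeric(axis_direction),
                 axis_point = as.numeric(axis_point)),
            class = "screw_symmetry")
}

#' @export
print.screw_symmetry <- function(x, ...) {
  cat(sprintf("<screw_symmetry> rise %.4f A/subunit, twist %.4f deg/subunit\n",
              x$rise, x$twist))
  cat(sprintf("  axis (%.3f, %.3f, %.3f) through (%.2f, %.2f, %.2f)\n",
              x$axis_direction[1], x$axis_direction[2], x$axis_direction[3],
              x$axis_point[1], x$axis_point[2], x$axis_point[3]))
  invisible(x)
}

#' Build a linear filament from a protomer and a screw symmetry
#'
#' Subunit `i` (0-based) carries the protomer coordinates rotated by
#' `i * twist` degrees about the axis and translated by `i * rise`
#' Angstrom along it, reproducing the linear stacking of subunits in the
#' filament. Chain identifiers run A, B, ..., Z, AA, ...
#'
#' @param protomer A [protomer_model()].
#' @param sym A [screw_symmetry()].
#' @param n Number of subunits (>= 1).
#'
#' @return An `assembly` tibble (topology `"linear"`) with the symmetry
#'   attached.
#' @export
#' @examples
#' p <- synth_protomer(seed = 1)
#' fil <- build_filament(p, screw_symmetry(20.95, -1.05), n = 5)
build_filament <- function(protomer, sym, n) {
  stopifnot(inherits(sym, "screw_symmetry"))
  if (!is.numeric(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  xyz <- as.matrix(protomer[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    bad <- which(rowSums(!is.finite(xyz)) > 0)[1]
    stop(sprintf("non-finite coordinates for atom %s of residue %d",
                 protomer$atom[bad], protomer$resno[bad]), call. = FALSE)
  }
  a <- sym$axis_direction
  p0 <- sym$axis_point
  chains <- chain_labels(n)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    k <- i - 1L
    R <- rotation_about_axis(a, deg2rad(sym$twist * k))
    xi <- apply_rigid(xyz, R, centre = p0, shift = k * sym$rise * a)
    sub <- protomer
    sub$chain <- chains[i]
    sub$x <- xi[, 1]; sub$y <- xi[, 2]; sub$z <- xi[, 3]
    pieces[[i]] <- tibble::as_tibble(sub)
  }
  out <- new_assembly(dplyr::bind_rows(pieces), "linear", sym, chains)
  attr(out, "helix_ranges") <- helix_ranges(protomer)
  out
}

#' Estimate screw parameters from an assembly
#'
#' Fits, for every consecutive subunit pair, the least-squares (Kabsch)
#' rigid transform mapping subunit i onto subunit i+1 over CA atoms, and
#' decomposes it into a rotation about and a translation along the screw
#' axis. Estimates are averaged over pairs (circular mean for the twist).
#' The axis is oriented so the rise is positive; the twist sign follows
#' the right-hand rule about that axis.
#'
#' @param assembly An `assembly` with >= 2 subunits and identical atom
#'   ordering across subunits.
#'
#' @return A `screw_fit` object (also a `screw_symmetry`) with elements
#'   `rise`, `twist`, `axis_direction`, `axis_point`, `rmsd` (mean
#'   superposition RMSD) and `pairs` (per-pair tibble).
#' @export
#' @examples
#' p <- synth_protomer(seed = 1)
#' fit <- estimate_screw(build_filament(p, screw_symmetry(20.95, -1.05), 10))
#' glance(fit)
estimate_screw <- function(assembly) {
  subs <- subunit_xyz(assembly, atom = "CA")
  if (length(subs) < 2) stop("need >= 2 subunits to estimate a screw", call. = FALSE)
  fits <- vector("list", length(subs) - 1)
  for (i in seq_len(length(subs) - 1)) {
    kf <- kabsch_fit(subs[[i]], subs[[i + 1]])
    dec <- screw_decompose(kf$R, kf$t)
    if (dec$degenerate) {
      stop("consecutive subunits related by a 180-degree rotation: ",
           "screw axis sign is ambiguous (degenerate)", call. = FALSE)
    }
    fits[[i]] <- tibble::tibble(
      pair = i, rise = dec$rise, twist = rad2deg(dec$angle), rmsd = kf$rmsd,
      axis_x = dec$axis[1], axis_y = dec$axis[2], axis_z = dec$axis[3],
      point_x = dec$point[1], point_y = dec$point[2], point_z = dec$point[3])
  }
  pairs <- dplyr::bind_rows(fits)
  axis <- unit_vector(c(mean(pairs$axis_x), mean(pairs$axis_y), mean(pairs$axis_z)))
  point <- c(mean(pairs$point_x), mean(pairs$point_y), mean(pairs$point_z))
  # re-anchor the axis point near the assembly for readability
  centroid <- colMeans(as.matrix(assembly[, c("x", "y", "z")]))
  point <- point + sum((centroid - point) * axis) * axis
  out <- screw_symmetry(rise = mean(pairs$rise),
                        twist = circular_mean_deg(pairs$twist),
                        axis_direction = axis, axis_point = point)
  out$rmsd <- mean(pairs$rmsd)
  out$pairs <- pairs
  class(out) <- c("screw_fit", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-pair screw fits
#'
#' @param x A `screw_fit` from [estimate_screw()].
#' @param ... Unused.
#' @return `tidy()` returns the per-consecutive-pair tibble of fitted rise,
#'   twist and superposition RMSD; `glance()` a one-row summary.
#' @method tidy screw_fit
#' @export
tidy.screw_fit <- function(x, ...) x$pairs

#' @rdname tidy.screw_fit
#' @method glance screw_fit
#' @export
glance.screw_fit <- function(x, ...) {
  tibble::tibble(rise = x$rise, twist = x$twist, rmsd = x$rmsd,
                 n_pairs = nrow(x$pairs))
}

#' Rearrange a filament into a closed ring
#'
#' Places `n` copies of the protomer at angles 2*pi*i/n on a circle of
#' radius `n * rise / (2 * pi)` in the plane normal to the membrane
#' normal (z), each rotated so its filament-propagation direction is
#' tangential. The intrinsic per-subunit filament twist is dropped on
#' closure (the subunits are re-arranged, not screw-propagated); the
#' residual twist is reported as the `closure_mismatch_deg` attribute.
#' Subunit centroids sit exactly on the placement circle, so consecutive
#' centroids are spaced `rise` apart along the arc.
#'
#' @inheritParams build_filament
#' @param n Number of subunits in the ring (>= 3), e.g. 45 for the in
#'   silico NINJ1 membrane pore.
#'
#' @return An `assembly` with topology `"ring"`. Attribute `ring_radius`
#'   holds `n * rise / (2 * pi)` in Angstrom.
#' @export
#' @examples
#' p <- synth_protomer(seed = 1)
#' ring <- close_ring(p, screw_symmetry(20.95, -1.05), n = 45)
#' attr(ring, "ring_radius")
close_ring <- function(protomer, sym, n) {
  stopifnot(inherits(sym, "screw_symmetry"))
  if (!is.numeric(n) || n < 3 || n != round(n)) {
    stop("ring closure needs n >= 3 subunits", call. = FALSE)
  }
  n <- as.integer(n)
  R_ring <- n * sym$rise / (2 * pi)
  xyz <- as.matrix(protomer[, c("x", "y", "z")])
  # canonical frame: propagation axis -> +y (tangent at angle 0)
  M <- rotation_between(sym$axis_direction, c(0, 1, 0))
  local <- sweep(xyz, 2, sym$axis_point) %*% t(M)
  # put the subunit centroid exactly on the circle at angle 0: (R, 0, z)
  ctr <- colMeans(local)
  local <- sweep(local, 2, c(ctr[1] - R_ring, ctr[2], 0))
  chains <- chain_labels(n)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    phi <- 2 * pi * (i - 1L) / n
    Rz <- rotation_about_axis(c(0, 0, 1), phi)
    xi <- local %*% t(Rz)
    sub <- protomer
    sub$chain <- chains[i]
    sub$x <- xi[, 1]; sub$y <- xi[, 2]; sub$z <- xi[, 3]
    pieces[[i]] <- tibble::as_tibble(sub)
  }
  out <- new_assembly(dplyr::bind_rows(pieces), "ring", sym, chains)
  attr(out, "ring_radius") <- R_ring
  attr(out, "closure_mismatch_deg") <- sym$twist * n
  attr(out, "helix_ranges") <- helix_ranges(protomer)
  out
}

#' Stack two antiparallel filaments via their hydrophobic faces
#'
#' Duplicates a linear filament, rotates the copy 180 degrees about the
#' axis perpendicular to both the filament axis and the hydrophobic-face
#' normal (through the filament centroid, so the copy overlays the same
#' axial span with its propagation direction reversed and its
#' hydrophobic face turned inward) and translates it by `separation`
#' along the face normal, reproducing the packing of two identical
#' filaments in an antiparallel arrangement stacked via their
#' hydrophobic faces.
#'
#' @param filament A linear `assembly` carrying a screw symmetry.
#' @param separation Translation along the face normal (Angstrom).
#' @param face_normal Unit 3-vector normal to the hydrophobic face. When
#'   `NULL`, it is computed from [assign_faces()] with `scale`.
#' @param scale Hydrophobicity scale used when `face_normal` is `NULL`.
#' @param clash_dist Minimum allowed interatomic distance between the two
#'   filaments (Angstrom); closer contacts raise an error naming the
#'   worst pair.
#'
#' @return An `assembly` with topology `"double_filament"`; attribute
#'   `filament_axes` holds the two (antiparallel) axis directions.
#' @export
stack_double_filament <- function(filament, separation, face_normal = NULL,
                                  scale = hydrophobicity_scale("kd"),
                                  clash_dist = 1.5) {
  if (!identical(assembly_topology(filament), "linear")) {
    stop("input must be a linear filament", call. = FALSE)
  }
  sym <- assembly_symmetry(filament)
  if (is.null(sym)) sym <- estimate_screw(filament)
  a <- sym$axis_direction
  if (is.null(face_normal)) {
    prof <- assign_faces(filament, scale = scale)
    az <- deg2rad(attr(prof, "face_azimuth"))
    basis <- axis_basis(a)
    face_normal <- cos(az) * basis$e1 + sin(az) * basis$e2
  }
  h <- face_normal - sum(face_normal * a) * a
  h <- unit_vector(h)
  flip <- unit_vector(c(a[2] * h[3] - a[3] * h[2],
                        a[3] * h[1] - a[1] * h[3],
                        a[1] * h[2] - a[2] * h[1]))
  xyz <- as.matrix(filament[, c("x", "y", "z")])
  R <- rotation_about_axis(flip, pi)
  xyz2 <- apply_rigid(xyz, R, centre = colMeans(xyz), shift = separation * h)
  worst <- min_cross_distance(xyz, xyz2, cutoff = max(5, clash_dist))
  if (worst$min_dist < clash_dist) {
    stop(sprintf(
      "clash: atoms %s %s%d (filament 1) and %s %s%d (filament 2) are %.2f A apart",
      filament$atom[worst$i], filament$chain[worst$i], filament$resno[worst$i],
      filament$atom[worst$j], filament$chain[worst$j], filament$resno[worst$j],
      worst$min_dist), call. = FALSE)
  }
  n_sub <- length(subunit_chains(filament))
  chains <- chain_labels(2L * n_sub)
  copy <- filament
  copy$x <- xyz2[, 1]; copy$y <- xyz2[, 2]; copy$z <- xyz2[, 3]
  copy$chain <- chains[n_sub + match(copy$chain, subunit_chains(filament))]
  atoms <- dplyr::bind_rows(tibble::as_tibble(filament), tibble::as_tibble(copy))
  out <- new_assembly(atoms, "double_filament", sym, chains)
  attr(out, "filament_axes") <- rbind(a, as.vector(R %*% a))
  attr(out, "face_normal") <- h
  attr(out, "helix_ranges") <- helix_ranges(filament)
  out
}

#' Subunit count from polymer and monomer mass
#'
#' Mass photometry of purified NINJ1 filaments indicates an average
#' polymer mass of around 1.3 MDa; with a 16-kDa monomer this implies a
#' stoichiometry of roughly 81 subunits.
#'
#' @param polymer_mass Polymer mass (Da, > 0).
#' @param monomer_mass Monomer mass (Da, > 0).
#' @param extra_mass Optional additive correction (Da) for detergent or
#'   tags, subtracted from the polymer mass before dividing.
#'
#' @return A one-row tibble with `ratio` and `n_subunits` (nearest
#'   integer).
#' @export
#' @examples
#' subunit_count_from_mass(1.3e6, 1.6e4)
subunit_count_from_mass <- function(polymer_mass, monomer_mass, extra_mass = 0) {
  if (!is.finite(polymer_mass) || polymer_mass <= 0 ||
      !is.finite(monomer_mass) || monomer_mass <= 0) {
    stop("masses must be positive", call. = FALSE)
  }
  ratio <- (polymer_mass - extra_mass) / monomer_mass
  tibble::tibble(ratio = ratio, n_subunits = as.integer(round(ratio)))
}

# Deterministic orthonormal basis (e1, e2) of the plane normal to axis a.
#' @noRd
axis_basis <- function(a) {
  a <- unit_vector(a)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vector(ref - sum(ref * a) * a)
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  list(e1 = e1, e2 = e2)
}
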