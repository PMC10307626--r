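# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive quantities by direct enumeration, not by calling
# the package's optimized code paths.

# O(n^2) DBSCAN on full distance matrix, same semantics as the package
# implementation (min_pts counts the point itself; FIFO expansion in row
# order; border points go to the first core cluster reaching them).
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  D <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  labels <- rep(NA_integer_, n)
  cid <- 0L
  for (p in seq_len(n)) {
    if (!is.na(labels[p])) next
    if (length(nb[[p]]) < min_pts) { labels[p] <- -1L; next }
    cid <- cid + 1L
    labels[p] <- cid
    queue <- setdiff(nb[[p]], p)
    k <- 1L
    while (k <= length(queue)) {
      q <- queue[k]; k <- k + 1L
      if (!is.na(labels[q]) && labels[q] != -1L) next
      labels[q] <- cid
      if (length(nb[[q]]) >= min_pts) {
        queue <- c(queue, nb[[q]][is.na(labels[nb[[q]]]) | labels[nb[[q]]] == -1L])
      }
    }
  }
  labels
}

# Exhaustive intra/inter CA distances for one residue pair.
brute_pair_distances <- function(assembly, i, j) {
  ca <- assembly[assembly$atom == "CA", ]
  chains <- unique(ca$chain)
  get <- function(ch, r) {
    row <- ca[ca$chain == ch & ca$resno == r, ]
    c(row$x, row$y, row$z)
  }
  d_intra <- sqrt(sum((get(chains[1], i) - get(chains[1], j))^2))
  d_inter <- Inf
  if (length(chains) > 1) {
    for (p in chains) for (q in chains) {
      if (p == q) next
      d <- sqrt(sum((get(p, i) - get(q, j))^2))
      d_inter <- min(d_inter, d)
    }
  } else {
    d_inter <- NA_real_
  }
  c(d_intra = d_intra, d_inter_min = d_inter)
}

# Direct complex-sum hydrophobic moment on mean-centred values.
brute_moment <- function(H, delta_deg) {
  k <- seq_along(H) - 1
  z <- sum((H - mean(H)) * exp(1i * k * delta_deg * pi / 180))
  Mod(z) / length(H)
}

# Random rigid motion (proper rotation + translation), seeded by caller.
random_rigid <- function() {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- stats::runif(1, 0, 2 * pi)
  list(R = ninjfil:::rotation_about_axis(axis, theta),
       t = stats::rnorm(3, sd = 50))
}

# Apply a rigid motion to any atom tibble, preserving class/attributes.
transform_atoms <- function(obj, rig) {
  xyz <- as.matrix(obj[, c("x", "y", "z")]) %*% t(rig$R)
  obj$x <- xyz[, 1] + rig$t[1]
  obj$y <- xyz[, 2] + rig$t[2]
  obj$z <- xyz[, 3] + rig$t[3]
  obj
}

# Apply the same rigid motion to a screw symmetry.
transform_sym <- function(sym, rig) {
  screw_symmetry(rise = sym$rise, twist = sym$twist,
                 axis_direction = as.vector(rig$R %*% sym$axis_direction),
                 axis_point = as.vector(rig$R %*% sym$axis_point) + rig$t)
}

# Minimal flat protomer: CA+CB per residue at given positions.
toy_protomer <- function(resno, resid, xyz_ca, xyz_cb = NULL) {
  if (is.null(xyz_cb)) xyz_cb <- xyz_ca + matrix(rep(c(0, 0, 1), each = length(resno)), ncol = 3)
  atoms <- tibble::tibble(
    atom = rep(c("CA", "CB"), each = length(resno)),
    resno = rep(resno, 2),
    resid = rep(resid, 2),
    chain = "A",
    x = c(xyz_ca[, 1], xyz_cb[, 1]),
    y = c(xyz_ca[, 2], xyz_cb[, 2]),
    z = c(xyz_ca[, 3], xyz_cb[, 3]))
  protomer_model(atoms, helix_ranges = list())
}

# Kabsch RMSD between two coordinate sets after optimal superposition.
superposed_rmsd <- function(X, Y) {
  ninjfil:::kabsch_fit(X, Y)$rmsd
}
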