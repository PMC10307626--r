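# Synthetic-data generators: every analysis stage in the package can be
# exercised without any experimental download. Each generator is a
# deterministic function of its arguments and a single `seed`; the global
# random stream is restored on exit.

#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy four-helix protomer
#'
#' Builds an idealized four-helix protomer emulating the NINJ1 subunit
#' fold for geometry tests: each annotated helix is an ideal alpha-helix
#' (1.5 Angstrom rise and 100 degrees per residue on a 2.3 Angstrom CA
#' radius, giving consecutive CA distances of ~3.8 Angstrom), helices
#' are packed antiparallel on a square lattice, and loop residues
#' connect them. Atoms are CA plus a pseudo side-chain CB displaced
#' radially outward. The default sequence alternates hydrophobic (Leu)
#' and polar (Ser) residues with the 100-degree helical period, so every
#' helix is amphipathic; loops are glycine.
#'
#' @param seed Integer seed; the same seed gives bitwise-identical
#'   coordinates.
#' @param helix_ranges Named helix intervals (default
#'   [ninj1_helix_ranges()], so alpha-3 spans residues 79-103).
#' @param residues Overall modelled interval (default 39-141, the
#'   ordered NINJ1 core).
#' @param jitter_sd Gaussian coordinate jitter in Angstrom (default
#'   0.05; the seed only changes this noise).
#' @param sequence Optional 1-letter sequence overriding the default
#'   pattern (must cover `residues`).
#'
#' @return A [protomer_model()].
#' @export
#' @examples
#' p <- synth_protomer(seed = 1)
#' nrow(p)
synth_protomer <- function(seed = 1, helix_ranges = ninj1_helix_ranges(),
                           residues = c(39L, 141L), jitter_sd = 0.05,
                           sequence = NULL) {
  with_seed(seed, {
    res <- seq(residues[1], residues[2])
    n_res <- length(res)
    # helix packing: axis along z, centres on a square lattice, alternating
    # up/down direction
    centres <- list(c(0, 0), c(8, 0), c(8, 8), c(0, 8))
    dirs <- c(1, -1, 1, -1)
    ca <- matrix(NA_real_, n_res, 3)
    cb <- matrix(NA_real_, n_res, 3)
    in_helix <- rep(FALSE, n_res)
    hr <- helix_ranges[order(vapply(helix_ranges, `[`, numeric(1), 1))]
    for (h in seq_along(hr)) {
      rng <- hr[[h]]
      idx <- which(res >= rng[1] & res <= rng[2])
      k <- seq_along(idx) - 1
      phi <- deg2rad(100 * k)
      zz <- dirs[h] * 1.5 * k
      cx <- centres[[h]][1]; cy <- centres[[h]][2]
      ca[idx, ] <- cbind(cx + 2.3 * cos(phi), cy + 2.3 * sin(phi), zz)
      cb[idx, ] <- cbind(cx + 3.8 * cos(phi), cy + 3.8 * sin(phi), zz)
      in_helix[idx] <- TRUE
    }
    # loops and termini: straight interpolation between anchors, spaced 3.8 A
    anchor <- which(in_helix)
    gaps <- which(!in_helix)
    for (g in gaps) {
      prev <- anchor[anchor < g]
      nxt <- anchor[anchor > g]
      if (length(prev) == 0) {
        ref <- ca[nxt[1], ]
        ca[g, ] <- ref + c(0, 0, -3.8 * (nxt[1] - g))
      } else if (length(nxt) == 0) {
        ref <- ca[prev[length(prev)], ]
        ca[g, ] <- ref + c(0, 0, 3.8 * (g - prev[length(prev)]))
      } else {
        p1 <- prev[length(prev)]; p2 <- nxt[1]
        w <- (g - p1) / (p2 - p1)
        ca[g, ] <- (1 - w) * ca[p1, ] + w * ca[p2, ]
      }
      cb[g, ] <- ca[g, ] + c(0.9, 0.9, 0.6)
    }
    if (is.null(sequence)) {
      aa <- rep("G", n_res)
      for (h in seq_along(hr)) {
        rng <- hr[[h]]
        idx <- which(res >= rng[1] & res <= rng[2])
        k <- seq_along(idx) - 1
        aa[idx] <- ifelse(cos(deg2rad(100 * k)) > 0, "L", "S")
      }
    } else {
      aa <- strsplit(sequence, "")[[1]]
      if (length(aa) != n_res) {
        stop("sequence length must match the modelled interval", call. = FALSE)
      }
    }
    resid3 <- unname(AA_123[aa])
    if (jitter_sd > 0) {
      ca <- ca + matrix(stats::rnorm(3 * n_res, sd = jitter_sd), n_res, 3)
      cb <- cb + matrix(stats::rnorm(3 * n_res, sd = jitter_sd), n_res, 3)
    }
    atoms <- tibble::tibble(
      atom = rep(c("CA", "CB"), each = n_res),
      resno = rep(res, 2),
      resid = rep(resid3, 2),
      chain = "A",
      x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]), z = c(ca[, 3], cb[, 3]))
    atoms <- atoms[order(atoms$resno, atoms$atom), ]
    protomer_model(atoms, helix_ranges = helix_ranges,
                   sequence = paste(aa, collapse = ""))
  })
}

#' Simulate a single-molecule localization field
#'
#' Generates localization tables with the statistical structure of
#' SMLM data from membrane-protein clusters: structured components
#' (isolated dots, round Gaussian clusters, or branched filamentous
#' clusters built by a branching, directionally persistent random walk)
#' decorated with multi-localization blinking (a geometric number of
#' localizations per binding site, each displaced by the localization
#' precision), plus a uniform background. Branched clusters with size
#' scale around a micrometre emulate the 500 nm to several-micrometre
#' assemblies of pyroptotic cells; small dots and round clusters emulate
#' the homogeneous distribution in live cells.
#'
#' @param components List of component specifications, each a list with
#'   `kind` (`"dot"`, `"round"` or `"branched_filament"`), `count`,
#'   `size_nm` (site-scatter scale: sd for round clusters, per-branch
#'   contour length for branched ones), `sites` (binding sites per cluster;
#'   dots always have 1), `locs_per_site` (geometric mean, >= 1) and
#'   `precision_nm` (localization precision sd).
#' @param field_size_um Field width and height in micrometres.
#' @param background_per_um2 Uniform background localization density.
#' @param step_nm,branch_prob,turn_sd_deg Branched-walk parameters:
#'   step length (default 20 nm), per-step branching probability
#'   (default 0.02) and per-step heading noise (degrees, default 10).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `x`, `y` (nm), `frame`, `precision`,
#'   `component` (ground-truth component id; 0 = background) and `kind`.
#'   Attributes `field_area_um2` and `field_size_um`.
#' @export
synth_localizations <- function(components, field_size_um = c(10, 10),
                                background_per_um2 = 0,
                                step_nm = 20, branch_prob = 0.02,
                                turn_sd_deg = 10, seed = 1) {
  with_seed(seed, {
    w <- field_size_um[1] * 1000; h <- field_size_um[2] * 1000
    area <- prod(field_size_um)
    out <- list()
    comp_id <- 0L
    for (comp in components) {
      kind <- comp$kind
      count <- comp$count
      if (is.null(count) || count == 0) next
      for (r in seq_len(count)) {
        comp_id <- comp_id + 1L
        centre <- c(stats::runif(1, 0.1 * w, 0.9 * w),
                    stats::runif(1, 0.1 * h, 0.9 * h))
        sites <- switch(kind,
          dot = matrix(centre, 1, 2),
          round = {
            ns <- comp$sites %||% 40L
            cbind(stats::rnorm(ns, centre[1], comp$size_nm),
                  stats::rnorm(ns, centre[2], comp$size_nm))
          },
          branched_filament = branched_walk_sites(centre, comp$size_nm,
                                                  step_nm, branch_prob,
                                                  turn_sd_deg),
          stop("unknown component kind: ", kind, call. = FALSE))
        m <- comp$locs_per_site %||% 3
        sigma <- comp$precision_nm %||% 15
        n_locs <- 1L + stats::rgeom(nrow(sites), prob = 1 / m)
        idx <- rep(seq_len(nrow(sites)), n_locs)
        n_tot <- length(idx)
        if (n_tot == 0) next
        out[[length(out) + 1L]] <- tibble::tibble(
          x = sites[idx, 1] + stats::rnorm(n_tot, sd = sigma),
          y = sites[idx, 2] + stats::rnorm(n_tot, sd = sigma),
          frame = sample.int(10000L, n_tot, replace = TRUE),
          precision = sigma,
          component = comp_id,
          kind = kind)
      }
    }
    n_bg <- stats::rpois(1, background_per_um2 * area)
    if (n_bg > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        x = stats::runif(n_bg, 0, w), y = stats::runif(n_bg, 0, h),
        frame = sample.int(10000L, n_bg, replace = TRUE),
        precision = 15, component = 0L, kind = "background")
    }
    locs <- if (length(out) > 0) dplyr::bind_rows(out) else
      tibble::tibble(x = numeric(), y = numeric(), frame = integer(),
                     precision = numeric(), component = integer(),
                     kind = character())
    attr(locs, "field_area_um2") <- area
    attr(locs, "field_size_um") <- field_size_um
    locs
  })
}

# Branching, directionally persistent random walk; returns site matrix.
# `size_nm` is the contour length of each branch: every active tip walks
# the full number of generations, so the cluster extent is set by the
# (mostly straight) primary branch and grows with side branches.
#' @noRd
branched_walk_sites <- function(centre, size_nm, step_nm, branch_prob,
                                turn_sd_deg) {
  n_gen <- max(5L, round(size_nm / step_nm))
  pts <- matrix(centre, 1, 2)
  tips <- list(list(pos = centre, heading = stats::runif(1, 0, 2 * pi)))
  for (gen in seq_len(n_gen)) {
    new_tips <- list()
    for (tip in tips) {
      heading <- tip$heading + stats::rnorm(1, sd = deg2rad(turn_sd_deg))
      pos <- tip$pos + step_nm * c(cos(heading), sin(heading))
      pts <- rbind(pts, pos)
      new_tips[[length(new_tips) + 1L]] <- list(pos = pos, heading = heading)
      if (stats::runif(1) < branch_prob && length(tips) < 8) {
        side <- sample(c(-1, 1), 1)
        new_tips[[length(new_tips) + 1L]] <-
          list(pos = pos, heading = heading + side * stats::runif(1, pi / 3, pi / 2))
      }
    }
    tips <- new_tips
  }
  pts
}

#' Study-condition localization field presets
#'
#' Component lists emulating the two imaged conditions: `"untreated"`
#' is a homogeneous field of small dots with a few small round
#' clusters; `"pyroptotic"` adds large branched filamentous clusters
#' (micrometre size scale) and fewer free dots. Pass the result to
#' [synth_localizations()].
#'
#' @param condition `"untreated"` or `"pyroptotic"`.
#' @return A list of component specifications.
#' @export
#' @examples
#' locs <- synth_localizations(field_components("pyroptotic"), seed = 7)
field_components <- function(condition = c("untreated", "pyroptotic")) {
  condition <- match.arg(condition)
  switch(condition,
    untreated = list(
      list(kind = "dot", count = 150, locs_per_site = 3, precision_nm = 15),
      list(kind = "round", count = 12, size_nm = 40, sites = 30,
           locs_per_site = 3, precision_nm = 15)),
    pyroptotic = list(
      list(kind = "dot", count = 60, locs_per_site = 3, precision_nm = 15),
      list(kind = "round", count = 6, size_nm = 40, sites = 30,
           locs_per_site = 3, precision_nm = 15),
      list(kind = "branched_filament", count = 16, size_nm = 1200,
           locs_per_site = 6, precision_nm = 15)))
}

#' Plant an evolutionary-coupling table on an assembly
#'
#' Samples residue pairs of an assembly into three planted categories
#' based on exhaustively enumerated CA distances: `inter` pairs whose
#' minimum inter-subunit distance is shorter than the intra-subunit
#' one (and within `max_dist`), `intra` pairs with the reverse
#' relation (intra within `max_dist`), and `far` pairs with both
#' distances beyond `max_dist`. Coupling scores are drawn uniformly in
#' `score_range`.
#'
#' @param assembly An `assembly` with >= 2 subunits.
#' @param n_intra,n_inter,n_far Planted pair counts per category.
#' @param score_range Uniform score range (all above the usual 0.5
#'   analysis threshold by default).
#' @param max_dist CA cutoff defining the categories (Angstrom).
#' @param min_seq_sep Minimum |i - j| sequence separation (default 5).
#' @param seed Integer seed.
#'
#' @return A tibble with `i`, `j`, `score` and ground-truth
#'   `true_label` (`intra_dominant`, `inter_dominant`, `excluded`),
#'   sorted by descending score.
#' @export
synth_ec_table <- function(assembly, n_intra = 20, n_inter = 9, n_far = 10,
                           score_range = c(0.6, 3), max_dist = 12,
                           min_seq_sep = 5, seed = 1) {
  chains <- subunit_chains(assembly)
  if (is.null(chains) || length(chains) < 2) {
    stop("planting needs an assembly with >= 2 subunits", call. = FALSE)
  }
  with_seed(seed, {
    subs <- ca_by_subunit(assembly)
    res <- as.integer(rownames(subs[[1]]))
    n_res <- length(res)
    # exhaustive enumeration over all residue pairs and subunit pairs
    d_intra <- as.matrix(stats::dist(subs[[1]]))
    d_inter <- matrix(Inf, n_res, n_res)
    for (p in seq_along(subs)) {
      for (q in seq_along(subs)) {
        if (p == q) next
        cross <- outer(rowSums(subs[[p]]^2), rowSums(subs[[q]]^2), `+`) -
          2 * tcrossprod(subs[[p]], subs[[q]])
        d_inter <- pmin(d_inter, sqrt(pmax(cross, 0)))
      }
    }
    ut <- which(upper.tri(d_intra), arr.ind = TRUE)
    sep_ok <- abs(res[ut[, 1]] - res[ut[, 2]]) >= min_seq_sep
    ut <- ut[sep_ok, , drop = FALSE]
    di <- d_intra[ut]; de <- d_inter[ut]
    cat_inter <- which(de < di & de <= max_dist)
    cat_intra <- which(di < de & di <= max_dist)
    cat_far <- which(pmin(di, de) > max_dist)
    pick <- function(cand, n, what) {
      if (length(cand) < n) {
        stop(sprintf("only %d candidate %s pairs available (%d requested)",
                     length(cand), what, n), call. = FALSE)
      }
      sample(cand, n)
    }
    sel <- c(if (n_inter > 0) pick(cat_inter, n_inter, "inter") else integer(0),
             if (n_intra > 0) pick(cat_intra, n_intra, "intra") else integer(0),
             if (n_far > 0) pick(cat_far, n_far, "far") else integer(0))
    labels <- c(rep("inter_dominant", n_inter), rep("intra_dominant", n_intra),
                rep("excluded", n_far))
    if (length(sel) == 0) {
      return(tibble::tibble(i = integer(), j = integer(), score = numeric(),
                            true_label = character()))
    }
    out <- tibble::tibble(
      i = res[ut[sel, 1]], j = res[ut[sel, 2]],
      score = stats::runif(length(sel), score_range[1], score_range[2]),
      true_label = labels)
    dplyr::arrange(out, dplyr::desc(.data$score))
  })
}

#' Simulate a three-phase dithionite-quench trace
#'
#' Generates a fluorescence time course following the proteoliposome
#' permeability protocol: a baseline (default 180 s), a post-dithionite
#' phase (default 500 s) decaying exponentially to the quenched
#' plateau, and a post-Triton phase (default 60 s) decaying to the
#' fully disrupted level, with optional Gaussian noise. The planted
#' permeability is the noiseless value of
#' `100 - 200 * (F_dit - F_triton) / (F_initial - F_triton)`; pass
#' `permeability` to position the dithionite plateau, or `f_dit`
#' directly.
#'
#' @param f_initial,f_triton Baseline and fully disrupted fluorescence
#'   levels.
#' @param permeability Planted permeability in percent (ignored when
#'   `f_dit` is given); 0 corresponds to the sealed-liposome midpoint
#'   plateau.
#' @param f_dit Dithionite plateau level (overrides `permeability`).
#' @param durations Named phase durations in seconds.
#' @param dt Sampling interval (s).
#' @param noise_sd Gaussian noise sd as a fraction of `f_initial`.
#' @param tau Exponential time constants (s) of the two transitions.
#' @param seed Integer seed.
#'
#' @return A trace tibble (`time`, `signal`, `phase`) for
#'   [liposome_permeability()]; attributes `planted_permeability` and
#'   `planted_levels`.
#' @export
#' @examples
#' tr <- synth_trace(permeability = 40, seed = 3)
#' liposome_permeability(tr)$permeability
synth_trace <- function(f_initial = 1, f_triton = 0.02, permeability = 50,
                        f_dit = NULL,
                        durations = c(baseline = 180, post_dithionite = 500,
                                      post_triton = 60),
                        dt = 1, noise_sd = 0, tau = c(20, 5), seed = 1) {
  stopifnot(all(durations > 0))
  if (is.null(f_dit)) {
    f_dit <- f_triton + (100 - permeability) / 200 * (f_initial - f_triton)
  }
  planted <- 100 - 200 * (f_dit - f_triton) / (f_initial - f_triton)
  with_seed(seed, {
    t1 <- durations[["baseline"]]
    t2 <- t1 + durations[["post_dithionite"]]
    t3 <- t2 + durations[["post_triton"]]
    time <- seq(0, t3, by = dt)
    phase <- cut(time, c(-Inf, t1, t2, Inf),
                 labels = c("baseline", "post_dithionite", "post_triton"))
    signal <- ifelse(
      time < t1, f_initial,
      ifelse(time < t2,
             f_dit + (f_initial - f_dit) * exp(-(time - t1) / tau[1]),
             f_triton + (f_dit - f_triton) * exp(-(time - t2) / tau[2])))
    if (noise_sd > 0) {
      signal <- signal + stats::rnorm(length(signal), sd = noise_sd * f_initial)
    }
    out <- tibble::tibble(time = time, signal = signal,
                          phase = as.character(phase))
    attr(out, "planted_permeability") <- planted
    attr(out, "planted_levels") <- c(f_initial = f_initial, f_dit = f_dit,
                                     f_triton = f_triton)
    out
  })
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
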