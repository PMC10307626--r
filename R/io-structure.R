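#' Read a protein structure file
#'
#' Reads a PDB or mmCIF coordinate file (via bio3d) into the package's
#' tabular representation. A single-chain file yields a `protomer`; a
#' multi-chain file yields an `assembly` whose subunits are the chains
#' in file order (topology `"linear"`, symmetry unset until
#' [estimate_screw()] is run).
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param helix_ranges Helix annotations attached to protomer output
#'   (default [ninj1_helix_ranges()]; set `NULL` to skip annotation
#'   checks).
#' @return A `protomer` or `assembly` tibble.
#' @export
read_structure <- function(path, helix_ranges = ninj1_helix_ranges()) {
  ext <- tolower(tools::file_ext(path))
  pdb <- switch(ext,
    cif = bio3d::read.cif(path),
    bio3d::read.pdb(path))
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  atoms <- tibble::tibble(
    atom = at$elety, resno = as.integer(at$resno), resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z)
  chains <- unique(atoms$chain)
  if (length(chains) == 1) {
    protomer_model(atoms, helix_ranges = helix_ranges %||% list())
  } else {
    new_assembly(atoms, "linear", NULL, chains)
  }
}

#' Write an assembly (or protomer) to a PDB file
#'
#' One chain per subunit, chain identifiers as stored (A, B, ..., AA,
#' ...). Two-letter chain identifiers are truncated to their last
#' character on write, the PDB format's single-character limit.
#'
#' @param x A `protomer` or `assembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  atoms <- tibble::as_tibble(x)
  chain <- substr(atoms$chain, nchar(atoms$chain), nchar(atoms$chain))
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$atom,
                   chain = chain)
  invisible(path)
}

#' Save or load a screw symmetry as JSON
#'
#' Sidecar serialization for [screw_symmetry()] objects.
#'
#' @param sym A `screw_symmetry`.
#' @param path JSON path.
#' @return `write_screw_json()` returns `path` invisibly;
#'   `read_screw_json()` returns a `screw_symmetry`.
#' @export
write_screw_json <- function(sym, path) {
  stopifnot(inherits(sym, "screw_symmetry"))
  jsonlite::write_json(list(rise = sym$rise, twist = sym$twist,
                            axis_direction = sym$axis_direction,
                            axis_point = sym$axis_point),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_screw_json
#' @export
read_screw_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  screw_symmetry(rise = obj$rise, twist = obj$twist,
                 axis_direction = obj$axis_direction,
                 axis_point = obj$axis_point)
}

#' Split a multi-chain assembly into individual filaments
#'
#' Deposited structures can contain more than one filament (the NINJ1
#' cryo-EM model holds two antiparallel filaments). Chains are walked
#' in file order and grouped into maximal runs whose consecutive-pair
#' screw fits agree within `rise_tol` relative rise; each run becomes
#' one linear filament.
#'
#' @param assembly A multi-chain `assembly`.
#' @param rise_tol Relative rise agreement within a filament (default
#'   0.1, i.e. 10%).
#' @return A list of linear `assembly` objects.
#' @export
split_filaments <- function(assembly, rise_tol = 0.1) {
  chains <- subunit_chains(assembly)
  if (length(chains) < 2) return(list(assembly))
  subs <- subunit_xyz(assembly, atom = "CA")
  rises <- rep(NA_real_, length(chains) - 1)
  for (i in seq_len(length(chains) - 1)) {
    kf <- kabsch_fit(subs[[i]], subs[[i + 1]])
    rises[i] <- screw_decompose(kf$R, kf$t)$rise
  }
  groups <- list(chains[1])
  for (i in seq_len(length(chains) - 1)) {
    prev_rises <- rises[seq_len(i - 1)]
    ref <- if (i > 1 && length(groups[[length(groups)]]) > 1) {
      rises[i - 1]
    } else NA_real_
    same <- if (is.na(ref)) TRUE else abs(rises[i] - ref) <= rise_tol * ref
    # a jump in fitted rise starts a new filament
    median_rise <- stats::median(rises, na.rm = TRUE)
    plausible <- rises[i] <= 2 * median_rise
    if (same && plausible) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], chains[i + 1])
    } else {
      groups[[length(groups) + 1]] <- chains[i + 1]
    }
  }
  lapply(groups, function(g) {
    sub <- assembly[assembly$chain %in% g, ]
    new_assembly(sub, "linear", NULL, g)
  })
}
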