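#' Construct a protomer model
#'
#' A protomer is one subunit of a helical polymer, stored as a tibble of
#' atom records (one row per atom) with the subunit sequence and helix
#' annotations attached as attributes. Coordinates are in Angstrom and
#' residues use author (1-based) numbering.
#'
#' @param atoms A data frame with columns `atom` (atom name, e.g. "CA"),
#'   `resno` (author residue number), `resid` (3-letter residue code),
#'   `chain` (chain identifier) and `x`, `y`, `z` (Angstrom).
#' @param helix_ranges Named list of inclusive residue intervals, e.g.
#'   `list(a1 = c(44, 55), a2 = c(58, 74), a3 = c(79, 103), a4 = c(114, 138))`
#'   (the four helices of the NINJ1 protomer). Ranges must be ascending and
#'   non-overlapping, and every annotated residue must carry a CA atom.
#' @param sequence Optional 1-letter sequence string; derived from the atom
#'   records when omitted.
#'
#' @return A tibble of class `protomer` with attributes `helix_ranges` and
#'   `sequence`.
#' @export
#' @examples
#' p <- synth_protomer(seed = 1)
#' helix_ranges(p)
protomer_model <- function(atoms, helix_ranges = ninj1_helix_ranges(),
                           sequence = NULL) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("atom", "resno", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    bad <- which(!stats::complete.cases(is.finite(xyz)) | rowSums(!is.finite(xyz)) > 0)[1]
    stop(sprintf("non-finite coordinates for atom %s of residue %s %d",
                 atoms$atom[bad], atoms$resid[bad], atoms$resno[bad]),
         call. = FALSE)
  }
  if (any(atoms$resno < 1)) stop("residue numbers must be >= 1", call. = FALSE)
  validate_helix_ranges(helix_ranges, atoms)
  if (is.null(sequence)) sequence <- derive_sequence(atoms)
  structure(atoms,
            class = c("protomer", class(tibble::tibble()))) |>
    `attr<-`("helix_ranges", helix_ranges) |>
    `attr<-`("sequence", sequence)
}

#' Helix annotations of the NINJ1 protomer
#'
#' The four alpha-helices of the structured NINJ1 core in author numbering:
#' alpha-1 spans residues 44-55, alpha-2 58-74 (the two membrane-inserting
#' amphipathic helices), alpha-3 79-103 and alpha-4 114-138 (the
#' transmembrane hairpin).
#'
#' @return Named list of inclusive residue intervals.
#' @export
ninj1_helix_ranges <- function() {
  list(a1 = c(44L, 55L), a2 = c(58L, 74L), a3 = c(79L, 103L), a4 = c(114L, 138L))
}

#' @noRd
validate_helix_ranges <- function(ranges, atoms = NULL) {
  if (length(ranges) == 0) return(invisible(TRUE))
  m <- do.call(rbind, ranges)
  if (any(m[, 2] < m[, 1])) stop("helix range end before start", call. = FALSE)
  if (nrow(m) > 1) {
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2])) {
      stop("helix ranges overlap or are not ascending", call. = FALSE)
    }
  }
  if (!is.null(atoms)) {
    ca <- atoms$resno[atoms$atom == "CA"]
    annotated <- unlist(lapply(ranges, function(r) seq(r[1], r[2])))
    absent <- setdiff(annotated, ca)
    if (length(absent) > 0) {
      stop("annotated residue(s) without a CA atom: ",
           paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA_123 <- stats::setNames(names(AA_321), AA_321)

#' @noRd
derive_sequence <- function(atoms) {
  ca <- atoms[atoms$atom == "CA", ]
  ca <- ca[order(ca$resno), ]
  paste(unname(AA_321[ca$resid]), collapse = "")
}

#' Accessors for protomer and assembly attributes
#'
#' `helix_ranges()` returns the named helix intervals, `protomer_sequence()`
#' the 1-letter sequence, `assembly_symmetry()` the stored
#' [screw_symmetry()] (or `NULL`), `assembly_topology()` one of `"linear"`,
#' `"ring"`, `"double_filament"`, and `subunit_chains()` the ordered chain
#' identifiers of an assembly.
#'
#' @param x A `protomer` or `assembly` object.
#' @return See each accessor's description.
#' @name accessors
#' @export
helix_ranges <- function(x) attr(x, "helix_ranges")

#' @rdname accessors
#' @export
protomer_sequence <- function(x) attr(x, "sequence")

#' @rdname accessors
#' @export
assembly_symmetry <- function(x) attr(x, "symmetry")

#' @rdname accessors
#' @export
assembly_topology <- function(x) attr(x, "topology")

#' @rdname accessors
#' @export
subunit_chains <- function(x) attr(x, "chains")

# Chain labels A..Z, AA, AB, ... for n subunits.
#' @noRd
chain_labels <- function(n) {
  single <- LETTERS
  if (n <= 26) return(single[seq_len(n)])
  double <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, double)[seq_len(n)]
}

#' @noRd
new_assembly <- function(atoms, topology, symmetry, chains) {
  structure(tibble::as_tibble(atoms),
            class = c("assembly", class(tibble::tibble()))) |>
    `attr<-`("topology", topology) |>
    `attr<-`("symmetry", symmetry) |>
    `attr<-`("chains", chains)
}

# Split an assembly into per-subunit coordinate matrices (CA only or all
# atoms), in stored chain order, checking identical atom ordering.
#' @noRd
subunit_xyz <- function(assembly, atom = NULL) {
  chains <- subunit_chains(assembly)
  if (is.null(chains)) chains <- unique(assembly$chain)
  rows <- if (is.null(atom)) rep(TRUE, nrow(assembly)) else assembly$atom == atom
  sub <- assembly[rows, ]
  out <- lapply(chains, function(ch) {
    s <- sub[sub$chain == ch, ]
    as.matrix(s[, c("x", "y", "z")])
  })
  n_atoms <- vapply(out, nrow, integer(1))
  if (length(unique(n_atoms)) != 1) {
    stop("subunits have mismatched atom counts (",
         paste(unique(n_atoms), collapse = ", "), ")", call. = FALSE)
  }
  names(out) <- chains
  out
}

#' @export
print.protomer <- function(x, ...) {
  hr <- helix_ranges(x)
  cat(sprintf("<protomer> %d atoms, %d residues, %d annotated helices\n",
              nrow(x), length(unique(x$resno)), length(hr)))
  NextMethod()
}

#' @export
print.assembly <- function(x, ...) {
  sym <- assembly_symmetry(x)
  cat(sprintf("<assembly> topology=%s, %d subunits, %d atoms\n",
              assembly_topology(x), length(subunit_chains(x)), nrow(x)))
  if (!is.null(sym)) {
    cat(sprintf("  symmetry: rise %.3f A/subunit, twist %.3f deg/subunit\n",
                sym$rise, sym$twist))
  }
  NextMethod()
}
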