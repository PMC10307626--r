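#' Read an evolutionary-coupling pair table
#'
#' Parses a CSV of residue-pair coupling scores (the output format of
#' EC-inference pipelines): two residue-index columns and one score
#' column. Column names `i`/`j` (or `res_i`/`res_j`, `pos1`/`pos2`) and
#' `score` (or `cn`, `ec`) are auto-detected; otherwise the first two
#' integer-valued columns and the first remaining numeric column are
#' used. Duplicated pairs ((i, j) and (j, i) are the same pair) keep the
#' maximum score. Malformed rows are skipped with a message.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `i`, `j` (`i < j`) and `score`, sorted
#'   by descending score. Attribute `n_skipped` counts dropped rows.
#' @export
read_coupling_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop("no parseable rows in ", path, call. = FALSE)
  nm <- tolower(names(raw))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit) > 0) hit[1] else NA_integer_
  }
  ci <- pick(c("i", "res_i", "resi", "pos1", "position1"))
  cj <- pick(c("j", "res_j", "resj", "pos2", "position2"))
  cs <- pick(c("score", "cn", "ec", "coupling", "ec_score"))
  if (is.na(ci) || is.na(cj)) {
    int_cols <- which(vapply(raw, function(x) {
      is.numeric(x) && all(x[is.finite(x)] == round(x[is.finite(x)]))
    }, logical(1)))
    if (length(int_cols) < 2) stop("cannot identify residue-index columns", call. = FALSE)
    ci <- int_cols[1]; cj <- int_cols[2]
  }
  if (is.na(cs)) {
    num_cols <- setdiff(which(vapply(raw, is.numeric, logical(1))), c(ci, cj))
    if (length(num_cols) < 1) stop("cannot identify a score column", call. = FALSE)
    cs <- num_cols[1]
  }
  tab <- suppressWarnings(tibble::tibble(i = as.numeric(raw[[ci]]),
                                         j = as.numeric(raw[[cj]]),
                                         score = as.numeric(raw[[cs]])))
  ok <- is.finite(tab$i) & is.finite(tab$j) & is.finite(tab$score) &
    tab$i == round(tab$i) & tab$j == round(tab$j) & tab$i != tab$j
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(n_skipped, " malformed row(s) skipped")
  }
  tab <- tab[ok, ]
  if (nrow(tab) == 0) stop("no parseable rows in ", path, call. = FALSE)
  tab <- dplyr::mutate(tab,
                       i2 = pmin(.data$i, .data$j),
                       j2 = pmax(.data$i, .data$j))
  out <- tab |>
    dplyr::group_by(.data$i2, .data$j2) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::transmute(i = as.integer(.data$i2), j = as.integer(.data$j2),
                     score = .data$score) |>
    dplyr::arrange(dplyr::desc(.data$score))
  attr(out, "n_skipped") <- n_skipped
  out
}

# CA coordinates per subunit as a list of matrices indexed by residue
# number (rows named by resno).
#' @noRd
ca_by_subunit <- function(assembly) {
  chains <- subunit_chains(assembly)
  if (is.null(chains)) chains <- unique(assembly$chain)
  ca <- assembly[assembly$atom == "CA", ]
  lapply(stats::setNames(chains, chains), function(ch) {
    s <- ca[ca$chain == ch, ]
    s <- s[order(s$resno), ]
    m <- as.matrix(s[, c("x", "y", "z")])
    rownames(m) <- s$resno
    m
  })
}

#' Intra- and inter-subunit CA distances of a residue pair
#'
#' `d_intra` is the CA(i)-CA(j) distance within one (reference) subunit;
#' all subunits are rigid copies, so it is subunit-independent.
#' `d_inter_min` is the minimum over all ordered subunit pairs (p != q)
#' of the CA(i in p)-CA(j in q) distance, `NA` for single-subunit input.
#'
#' @param assembly An `assembly`.
#' @param i,j Author residue numbers of the pair.
#' @return A one-row tibble with `i`, `j`, `d_intra`, `d_inter_min`.
#' @export
pair_distances <- function(assembly, i, j) {
  subs <- ca_by_subunit(assembly)
  key_i <- as.character(i); key_j <- as.character(j)
  for (s in subs) {
    if (!key_i %in% rownames(s)) {
      stop("residue ", i, " has no CA atom in every subunit", call. = FALSE)
    }
    if (!key_j %in% rownames(s)) {
      stop("residue ", j, " has no CA atom in every subunit", call. = FALSE)
    }
  }
  d_intra <- sqrt(sum((subs[[1]][key_i, ] - subs[[1]][key_j, ])^2))
  d_inter <- NA_real_
  if (length(subs) > 1) {
    d_inter <- Inf
    for (p in seq_along(subs)) {
      for (q in seq_along(subs)) {
        if (p == q) next
        d <- sqrt(sum((subs[[p]][key_i, ] - subs[[q]][key_j, ])^2))
        if (d < d_inter) d_inter <- d
      }
    }
  }
  tibble::tibble(i = i, j = j, d_intra = d_intra, d_inter_min = d_inter)
}

# Vectorized distances for many pairs: distance matrices per subunit pair.
#' @noRd
all_pair_distances <- function(assembly, pairs) {
  subs <- ca_by_subunit(assembly)
  res <- rownames(subs[[1]])
  ii <- match(as.character(pairs$i), res)
  jj <- match(as.character(pairs$j), res)
  if (anyNA(ii) || anyNA(jj)) {
    missing_res <- unique(c(pairs$i[is.na(ii)], pairs$j[is.na(jj)]))
    stop("residue(s) without a CA atom: ",
         paste(utils::head(missing_res, 5), collapse = ", "), call. = FALSE)
  }
  cross_d <- function(A, B) {
    # distances between A[ii, ] and B[jj, ] elementwise
    sqrt(rowSums((A[ii, , drop = FALSE] - B[jj, , drop = FALSE])^2))
  }
  d_intra <- cross_d(subs[[1]], subs[[1]])
  d_inter <- rep(NA_real_, nrow(pairs))
  if (length(subs) > 1) {
    d_inter <- rep(Inf, nrow(pairs))
    for (p in seq_along(subs)) {
      for (q in seq_along(subs)) {
        if (p == q) next
        d_inter <- pmin(d_inter, cross_d(subs[[p]], subs[[q]]))
      }
    }
  }
  tibble::tibble(d_intra = d_intra, d_inter_min = d_inter)
}

#' Classify coupling pairs as intra- versus inter-protomer contacts
#'
#' Keeps the `top_n` pairs with coupling score above `score_min`,
#' measures intra- and minimum inter-subunit CA distances on the
#' assembly, and labels each pair:
#' \itemize{
#'   \item `excluded` when both distances exceed `max_dist` (contacts
#'     above 12 Angstrom between CA atoms are not considered);
#'   \item `inter_dominant` when the intermolecular distance is strictly
#'     shorter than the intramolecular one;
#'   \item `intra_dominant` otherwise (ties count as intra).
#' }
#' On the NINJ1 filament, nine of the top 100 pairs with score > 0.5 are
#' closer between subunits than within one monomer, including F127-G95.
#'
#' @param assembly An `assembly`.
#' @param pairs Tibble with columns `i`, `j`, `score` (see
#'   [read_coupling_table()]).
#' @param top_n Number of top-scoring pairs analysed (default 100).
#' @param score_min Minimum coupling score, exclusive (default 0.5).
#' @param max_dist CA distance cutoff in Angstrom (default 12).
#' @param offset Added to the pair indices to map alignment columns to
#'   author numbering (default 0).
#'
#' @return A tibble (descending score) with columns `i`, `j`, `score`,
#'   `d_intra`, `d_inter_min`, `label`; attribute `summary` is a one-row
#'   tibble of counts (`n_analysed`, `n_inter`, `n_intra`, `n_excluded`).
#' @export
classify_pairs <- function(assembly, pairs, top_n = 100, score_min = 0.5,
                           max_dist = 12, offset = 0) {
  empty <- tibble::tibble(i = integer(), j = integer(), score = numeric(),
                          d_intra = numeric(), d_inter_min = numeric(),
                          label = character())
  summary0 <- tibble::tibble(n_analysed = 0L, n_inter = 0L, n_intra = 0L,
                             n_excluded = 0L)
  if (is.null(pairs) || nrow(pairs) == 0) {
    attr(empty, "summary") <- summary0
    return(empty)
  }
  pairs <- tibble::as_tibble(pairs)
  pairs <- dplyr::arrange(pairs, dplyr::desc(.data$score))
  keep <- pairs[pairs$score > score_min, , drop = FALSE]
  keep <- utils::head(keep, top_n)
  if (nrow(keep) == 0) {
    attr(empty, "summary") <- summary0
    return(empty)
  }
  keep$i <- keep$i + offset
  keep$j <- keep$j + offset
  d <- all_pair_distances(assembly, keep)
  out <- dplyr::bind_cols(keep[, c("i", "j", "score")], d)
  min_d <- ifelse(is.na(out$d_inter_min), out$d_intra,
                  pmin(out$d_intra, out$d_inter_min))
  out$label <- dplyr::case_when(
    min_d > max_dist ~ "excluded",
    !is.na(out$d_inter_min) & out$d_inter_min < out$d_intra ~ "inter_dominant",
    TRUE ~ "intra_dominant")
  attr(out, "summary") <- tibble::tibble(
    n_analysed = nrow(out),
    n_inter = sum(out$label == "inter_dominant"),
    n_intra = sum(out$label == "intra_dominant"),
    n_excluded = sum(out$label == "excluded"))
  out
}

#' @rdname classify_pairs
#' @param x A classification tibble from `classify_pairs()`.
#' @export
coupling_summary <- function(x) attr(x, "summary")
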