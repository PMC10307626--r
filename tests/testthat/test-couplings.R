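# Planted two-subunit assembly: residue 1 of subunit A sits 5 A from
# residue 2 of subunit B, while the intra-subunit 1-2 distance is 30 A.
planted_assembly <- function() {
  ca <- rbind(c(0, 0, 0), c(30, 0, 0))   # residues 1, 2 of one subunit
  p <- toy_protomer(1:2, c("ALA", "GLY"), ca)
  # second subunit shifted so that res 2 of B is 5 A from res 1 of A
  b <- p
  b$x <- b$x - 25
  b$y <- b$y + 0
  b$chain <- "B"
  atoms <- dplyr::bind_rows(tibble::as_tibble(p), tibble::as_tibble(b))
  ninjfil:::new_assembly(atoms, "linear", NULL, c("A", "B"))
}

test_that("pair_distances matches a planted construction", {
  asm <- planted_assembly()
  d <- pair_distances(asm, 1, 2)
  expect_equal(d$d_intra, 30)
  expect_equal(d$d_inter_min, 5)
})

test_that("the intra distance is subunit-independent on rigid copies", {
  p <- synth_protomer(seed = 2)
  asm <- build_filament(p, screw_symmetry(20.95, -1.05), 4)
  ca <- asm[asm$atom == "CA", ]
  d_by_chain <- vapply(subunit_chains(asm), function(ch) {
    s <- ca[ca$chain == ch, ]
    sqrt(sum((unlist(s[s$resno == 58, c("x", "y", "z")]) -
                unlist(s[s$resno == 127, c("x", "y", "z")]))^2))
  }, numeric(1))
  expect_lt(diff(range(d_by_chain)), 1e-6)
})

test_that("pair_distances matches exhaustive enumeration on small assemblies", {
  p <- synth_protomer(seed = 3)
  for (n_sub in 2:5) {
    asm <- build_filament(p, screw_symmetry(20.95, -1.05), n_sub)
    for (pr in list(c(44, 120), c(58, 95), c(79, 138))) {
      got <- pair_distances(asm, pr[1], pr[2])
      want <- brute_pair_distances(asm, pr[1], pr[2])
      expect_equal(got$d_intra, unname(want["d_intra"]), tolerance = 1e-9)
      expect_equal(got$d_inter_min, unname(want["d_inter_min"]), tolerance = 1e-9)
    }
  }
})

test_that("single-subunit assemblies have no inter distance", {
  p <- synth_protomer(seed = 1)
  asm <- build_filament(p, screw_symmetry(20.95, -1.05), 1)
  d <- pair_distances(asm, 44, 50)
  expect_true(is.na(d$d_inter_min))
  cls <- classify_pairs(asm, tibble::tibble(i = 44, j = 50, score = 1),
                        max_dist = 12)
  expect_true(cls$label %in% c("intra_dominant", "excluded"))
})

test_that("missing CA atoms are rejected naming the residue", {
  asm <- planted_assembly()
  expect_error(pair_distances(asm, 1, 99), "99")
})

test_that("d_inter_min is monotone non-increasing as subunits are added", {
  p <- synth_protomer(seed = 4)
  pairs <- list(c(44, 127), c(95, 127), c(60, 138))
  prev <- rep(Inf, length(pairs))
  for (n_sub in 2:6) {
    asm <- build_filament(p, screw_symmetry(20.95, -1.05), n_sub)
    cur <- vapply(pairs, function(pr) pair_distances(asm, pr[1], pr[2])$d_inter_min,
                  numeric(1))
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("classification labels follow the distance rules", {
  asm <- planted_assembly()
  # (30, 5): inter closer and within cutoff -> inter_dominant
  cls <- classify_pairs(asm, tibble::tibble(i = 1, j = 2, score = 1))
  expect_identical(cls$label, "inter_dominant")
  # both distances above 12 A -> excluded, even though inter < intra
  ca <- rbind(c(0, 0, 0), c(14, 0, 0))
  p <- toy_protomer(1:2, c("ALA", "GLY"), ca)
  b <- p; b$chain <- "B"; b$y <- b$y + 13
  asm2 <- ninjfil:::new_assembly(
    dplyr::bind_rows(tibble::as_tibble(p), tibble::as_tibble(b)),
    "linear", NULL, c("A", "B"))
  d2 <- pair_distances(asm2, 1, 2)
  expect_gt(d2$d_intra, 12)
  expect_gt(d2$d_inter_min, 12)
  cls2 <- classify_pairs(asm2, tibble::tibble(i = 1, j = 2, score = 1))
  expect_identical(cls2$label, "excluded")
})

test_that("exact ties between intra and inter count as intra (strict rule)", {
  ca <- rbind(c(0, 0, 0), c(8, 0, 0))
  p <- toy_protomer(1:2, c("ALA", "GLY"), ca)
  b <- p; b$chain <- "B"; b$x <- b$x - 16   # res2(B) at -8: |inter| = 8 = intra
  asm <- ninjfil:::new_assembly(
    dplyr::bind_rows(tibble::as_tibble(p), tibble::as_tibble(b)),
    "linear", NULL, c("A", "B"))
  d <- pair_distances(asm, 1, 2)
  expect_equal(d$d_intra, d$d_inter_min)
  cls <- classify_pairs(asm, tibble::tibble(i = 1, j = 2, score = 1))
  expect_identical(cls$label, "intra_dominant")
})

test_that("empty pair lists classify to empty output with zero counts", {
  asm <- planted_assembly()
  cls <- classify_pairs(asm, tibble::tibble(i = integer(), j = integer(),
                                            score = numeric()))
  expect_equal(nrow(cls), 0)
  expect_equal(coupling_summary(cls)$n_analysed, 0L)
  expect_equal(coupling_summary(cls)$n_inter, 0L)
})

test_that("top-n and score filters follow the analysis protocol", {
  p <- synth_protomer(seed = 5)
  asm <- build_filament(p, screw_symmetry(20.95, -1.05), 3)
  tab <- synth_ec_table(asm, n_intra = 10, n_inter = 5, n_far = 5, seed = 2)
  # drop scores below threshold
  low <- tab
  low$score[1:3] <- 0.2
  cls <- classify_pairs(asm, low, top_n = 100, score_min = 0.5)
  expect_equal(nrow(cls), nrow(tab) - 3)
  # top_n truncation keeps the highest scores in descending order
  cls5 <- classify_pairs(asm, tab, top_n = 5)
  expect_equal(nrow(cls5), 5)
  expect_equal(cls5$score, sort(tab$score, decreasing = TRUE)[1:5])
  expect_true(all(diff(cls5$score) <= 0))
})

test_that("classifier recovers all planted labels exactly", {
  p <- synth_protomer(seed = 6)
  asm <- build_filament(p, screw_symmetry(20.95, -1.05), 4)
  for (seed in 1:5) {
    tab <- synth_ec_table(asm, n_intra = 15, n_inter = 9, n_far = 8, seed = seed)
    cls <- classify_pairs(asm, tab, top_n = 100, score_min = 0.5, max_dist = 12)
    merged <- dplyr::inner_join(cls, tab, by = c("i", "j"))
    expect_equal(nrow(merged), nrow(tab))
    expect_identical(merged$label, merged$true_label)
    expect_equal(coupling_summary(cls)$n_inter, 9L)
  }
})

test_that("classification is invariant under rigid motion and subunit relabelling", {
  set.seed(11)
  p <- synth_protomer(seed = 7)
  asm <- build_filament(p, screw_symmetry(20.95, -1.05), 3)
  tab <- synth_ec_table(asm, n_intra = 8, n_inter = 4, n_far = 4, seed = 3)
  base <- classify_pairs(asm, tab)
  moved <- transform_atoms(asm, random_rigid())
  cls_m <- classify_pairs(moved, tab)
  expect_equal(cls_m$d_intra, base$d_intra, tolerance = 1e-9)
  expect_equal(cls_m$d_inter_min, base$d_inter_min, tolerance = 1e-9)
  expect_identical(cls_m$label, base$label)
  # relabel subunits (reverse chain order)
  rev_chains <- rev(subunit_chains(asm))
  relab <- ninjfil:::new_assembly(tibble::as_tibble(asm), "linear", NULL,
                                  rev_chains)
  cls_r <- classify_pairs(relab, tab)
  expect_equal(cls_r$d_inter_min, base$d_inter_min, tolerance = 1e-9)
  expect_identical(cls_r$label, base$label)
})

test_that("coupling tables read with deduplication and malformed-row skipping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("i,j,score",
               "10,20,0.9",
               "20,10,0.7",
               "30,40,1.2",
               "bad,50,0.3",
               "15,15,2.0"), path)
  expect_message(tab <- read_coupling_table(path), "2 malformed")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$score[tab$i == 10 & tab$j == 20], 0.9)
  expect_equal(attr(tab, "n_skipped"), 2)
})

test_that("a generated coupling table round-trips through CSV losslessly", {
  p <- synth_protomer(seed = 8)
  asm <- build_filament(p, screw_symmetry(20.95, -1.05), 3)
  tab <- synth_ec_table(asm, n_intra = 6, n_inter = 3, n_far = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab[, c("i", "j", "score")], path)
  back <- read_coupling_table(path)
  orig <- dplyr::arrange(tibble::tibble(i = pmin(tab$i, tab$j),
                                        j = pmax(tab$i, tab$j),
                                        score = tab$score),
                         dplyr::desc(score))
  expect_equal(back$i, orig$i)
  expect_equal(back$j, orig$j)
  expect_equal(back$score, orig$score, tolerance = 1e-12)
})

test_that("files with no parseable rows are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("i,j,score", "a,b,c"), path)
  expect_error(suppressMessages(read_coupling_table(path)), "no parseable")
})
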