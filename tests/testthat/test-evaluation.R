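water_struct <- function(xyz) {
  m <- matrix(xyz, ncol = 3, byrow = TRUE)
  tibble::tibble(
    serial = seq_len(nrow(m)), name = "O", resid = "HOH", chain = "A",
    resno = seq_len(nrow(m)), x = m[, 1], y = m[, 2], z = m[, 3],
    element = "O", record_kind = "water"
  )
}

test_that("find_consensus merges replicate waters within 1 A", {
  s1 <- water_struct(c(0, 0, 0, 8, 0, 0))
  s2 <- water_struct(c(0.5, 0, 0))
  cs <- find_consensus(list(s1, s2))

  expect_equal(nrow(cs$consensus), 1)
  expect_equal(cs$consensus$support, 2)
  expect_equal(cs$consensus$x, 0.25)
  expect_equal(nrow(cs$singletons), 1)
  expect_equal(cs$singletons$x, 8)

  expect_error(find_consensus(list(s1)), "at least 2")
})

test_that("consensus support counts are invariant to structure order", {
  specs <- fixture_spec(n_sites = 4, n_singletons = 3, seed = 31)
  reps <- make_replicates(specs)
  a <- find_consensus(reps)
  b <- find_consensus(rev(reps))
  expect_equal(a$consensus[c("x", "y", "z", "support")],
               b$consensus[c("x", "y", "z", "support")], tolerance = 1e-12)
  expect_equal(a$singletons, b$singletons, tolerance = 1e-12)
})

test_that("two waters of the same structure do not form a consensus", {
  s1 <- water_struct(c(0, 0, 0, 0.5, 0, 0))
  s2 <- water_struct(c(20, 0, 0))
  cs <- find_consensus(list(s1, s2))
  expect_equal(nrow(cs$consensus), 0)
  expect_equal(nrow(cs$singletons), 2)
})

test_that("evaluation counts TPs once and FPs by one-to-one matching", {
  cs <- structure(list(
    consensus = tibble::tibble(x = c(0, 5), y = 0, z = 0, support = c(2L, 2L)),
    singletons = tibble::tibble(x = double(), y = double(), z = double())
  ), class = "consensus_set")

  # predictions exactly on the consensus waters: all found, zero error
  exact <- tibble::tibble(x = c(0, 5), y = 0, z = 0)
  r <- evaluate_predictions(exact, cs, max_error = 2)
  expect_equal(r$n_predicted_consensus, 2L)
  expect_equal(r$pct_consensus_predicted, 100)
  expect_equal(r$n_false_positives, 0L)
  expect_equal(r$mean_error, 0)

  # a stray prediction is a false positive
  stray <- tibble::tibble(x = c(0, 5, 50), y = 0, z = 0)
  expect_equal(evaluate_predictions(stray, cs, 2)$n_false_positives, 1L)

  # one water flanked by two predictions: one TP, one FP
  flank <- structure(list(
    consensus = tibble::tibble(x = 0, y = 0, z = 0, support = 2L),
    singletons = tibble::tibble(x = double(), y = double(), z = double())
  ), class = "consensus_set")
  two <- tibble::tibble(x = c(-1, 1), y = 0, z = 0)
  r2 <- evaluate_predictions(two, flank, max_error = 1.5)
  expect_equal(r2$n_predicted_consensus, 1L)
  expect_equal(r2$n_false_positives, 1L)

  # prediction order does not matter
  r3 <- evaluate_predictions(two[2:1, ], flank, max_error = 1.5)
  expect_equal(r3, r2)
})

test_that("TP + unmatched consensus equals the consensus count", {
  spec <- fixture_spec(n_sites = 4, n_singletons = 2, seed = 44)
  reps <- make_replicates(spec)
  cs <- find_consensus(reps)
  sites <- predict_sites(make_poses(spec))
  r <- evaluate_predictions(sites, cs, max_error = 2)
  expect_equal(r$n_consensus, nrow(cs$consensus))
  expect_lte(r$n_predicted_consensus, r$n_consensus)
})

test_that("the hydration-shell filter drops far-from-protein waters", {
  protein <- atom_row(0, 0, 0, element = "C", name = "CB", resid = "ALA",
                      acceptor = FALSE)
  cs <- structure(list(
    consensus = tibble::tibble(x = c(2, 9), y = 0, z = 0, support = c(2L, 2L)),
    singletons = tibble::tibble(x = double(), y = double(), z = double())
  ), class = "consensus_set")
  r <- evaluate_predictions(tibble::tibble(x = 2, y = 0, z = 0), cs,
                            max_error = 2, protein = protein,
                            protein_dist_filter = 3.3)
  expect_equal(r$n_consensus, 1L)
  expect_equal(r$n_predicted_consensus, 1L)
})

test_that("the random baseline is reproducible, clash-free and box-bound", {
  pocket <- make_pocket(fixture_spec(seed = 2))
  box <- site_box(colMeans(pocket[, c("x", "y", "z")]), side = 12)
  p1 <- random_baseline(pocket, box, n = 100, seed = 9)
  p2 <- random_baseline(pocket, box, n = 100, seed = 9)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 100)

  heavy <- pocket[pocket$element != "H", ]
  d <- waterplace:::cross_dist(p1, heavy)
  radsum <- default_vdw_radii()[heavy$element] + default_vdw_radii()[["O"]]
  expect_true(all(sweep(d, 2, radsum, `-`) >= 0))
  expect_true(all(abs(p1$x - box$center[1]) <= 6 + 1e-9))

  # an empty structure allows every node
  empty <- pocket[0, ]
  expect_equal(nrow(random_baseline(empty, site_box(c(0, 0, 0), 6),
                                    n = 50, seed = 1)), 50)

  # a box packed with atoms leaves too few nodes and warns
  dense <- tibble::tibble(
    serial = 1:27, name = "CB", resid = "ALA", chain = "A", resno = 1:27,
    x = rep(c(-2, 0, 2), 9), y = rep(rep(c(-2, 0, 2), each = 3), 3),
    z = rep(c(-2, 0, 2), each = 9), element = "C", record_kind = "protein"
  )
  expect_warning(
    few <- random_baseline(dense, site_box(c(0, 0, 0), side = 4), n = 50,
                           seed = 1),
    "clash-free"
  )
  expect_lt(nrow(few), 50)
})

test_that("error distributions report per-point minimum distances", {
  ref <- tibble::tibble(x = c(0, 10), y = 0, z = 0)
  pts <- tibble::tibble(x = c(0, 3, 9), y = c(0, 4, 0), z = 0)
  ed <- error_distribution(pts, ref)
  expect_equal(ed$min_dist, c(0, 5, 1))
  expect_error(error_distribution(pts, ref[0, ]), "empty")
})

test_that("predicted sites beat the random baseline on the synthetic pocket", {
  spec <- fixture_spec(seed = 61)
  pocket <- make_pocket(spec)
  sites <- predict_sites(make_poses(spec))
  reference <- tibble::tibble(x = spec$sites[, 1], y = spec$sites[, 2],
                              z = spec$sites[, 3])
  box <- site_box(colMeans(reference), side = 15)
  rnd <- random_baseline(pocket, box, n = 200, seed = 5)

  d_pred <- error_distribution(sites, reference)$min_dist
  d_rnd <- error_distribution(rnd, reference)$min_dist
  expect_lt(median(d_pred), median(d_rnd))
})

test_that("propensity profiles are per-class cumulative occupancy curves", {
  sites <- tibble::tibble(x = 0, y = 0, z = 0)
  lig <- dplyr::bind_rows(
    atom_row(0, 0, 0, element = "O", name = "O1", resid = "LIG",
             record_kind = "ligand", serial = 1),
    atom_row(3, 0, 0, element = "C", name = "C1", resid = "LIG",
             record_kind = "ligand", acceptor = FALSE, serial = 2)
  )
  prof <- propensity_profile(sites, lig, cutoffs = c(0.5, 1, 2, 3, 4))
  o_row <- prof[prof$group == "acceptor" & prof$cutoff == 0.5, ]
  c_row <- prof[prof$group == "carbon_nonaromatic" & prof$cutoff == 0.5, ]
  expect_equal(o_row$probability, 1)
  expect_equal(c_row$probability, 0)
  expect_true(all(prof$probability >= 0 & prof$probability <= 1))
  for (g in unique(prof$group)) {
    expect_true(all(diff(prof$probability[prof$group == g]) >= 0))
  }
})

test_that("a planted 9:1 polar/carbon occupancy ratio is recovered", {
  sites <- tibble::tibble(x = seq(0, 45, by = 5), y = 0, z = 0)  # 10 sites
  on_site <- function(i, el, n) {
    purrr::map(seq_len(n), function(j) {
      atom_row(sites$x[i[j]], 0.1, 0, element = el,
               name = paste0(el, j), resid = "LIG", record_kind = "ligand",
               acceptor = el == "O", serial = j)
    }) |> dplyr::bind_rows()
  }
  # 9 of 10 polar atoms sit on sites; 1 of 10 carbons does
  polar <- dplyr::bind_rows(on_site(1:9, "O", 9),
                            atom_row(2.5, 0, 0, element = "O", name = "Ofar",
                                     resid = "LIG", record_kind = "ligand",
                                     serial = 99))
  carbon <- dplyr::bind_rows(
    on_site(10, "C", 1),
    purrr::map(1:9, function(j) {
      atom_row(2.5 + 5 * (j - 1), 2.5, 0, element = "C",
               name = paste0("Cfar", j), resid = "LIG",
               record_kind = "ligand", acceptor = FALSE, serial = 100 + j)
    }) |> dplyr::bind_rows()
  )
  prof <- propensity_profile(sites, dplyr::bind_rows(polar, carbon),
                             cutoffs = c(0.5, 1.5))
  p_o <- prof$probability[prof$group == "acceptor" & prof$cutoff == 0.5]
  p_c <- prof$probability[prof$group == "carbon_nonaromatic" &
                            prof$cutoff == 0.5]
  expect_equal(p_o / p_c, 9, tolerance = 1e-9)
})

test_that("empty ligand classes are omitted with a note", {
  sites <- tibble::tibble(x = 0, y = 0, z = 0)
  lig <- atom_row(0.2, 0, 0, element = "O", name = "O1", resid = "LIG",
                  record_kind = "ligand")
  expect_message(prof <- propensity_profile(sites, lig), "omitted")
  expect_false("carbon_nonaromatic" %in% prof$group)
})
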