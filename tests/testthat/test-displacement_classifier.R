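make_ligand_atom <- function(x, y, z, element = "C") {
  atom_row(x, y, z, element = element,
           name = paste0(element, "1"), resid = "LIG",
           record_kind = "ligand",
           acceptor = element %in% c("O", "N"))
}

test_that("label_sites applies the 1.5 A conserved/displaced/ambiguous rules", {
  sites <- tibble::tibble(site = 1:3,
                          x = c(0, 10, 20), y = 0, z = 0)
  waters <- tibble::tibble(x = 1.2, y = 0, z = 0)           # 1.2 A from site 1
  ligand <- make_ligand_atom(10.8, 0, 0)                    # 0.8 A from site 2

  lab <- label_sites(sites, waters, ligand)
  expect_equal(lab$class, c("conserved", "displaced", "ambiguous"))
  expect_equal(lab$displaced_by, c(NA, "nonpolar", NA))
  expect_equal(lab$match_distance[1:2], c(1.2, 0.8))

  # a polar nearest ligand atom flips the displacement type
  lab2 <- label_sites(sites[2, ], waters, make_ligand_atom(10.8, 0, 0, "O"))
  expect_equal(lab2$displaced_by, "polar")

  # nearest-atom rule decides when polar and non-polar both overlap
  both <- dplyr::bind_rows(make_ligand_atom(10.6, 0, 0, "O"),
                           make_ligand_atom(10.9, 0, 0, "C"))
  expect_equal(label_sites(sites[2, ], waters, both)$displaced_by, "polar")
})

test_that("label_sites is order-independent and idempotent", {
  spec <- fixture_spec(overlap_plan = c("conserved", "polar", "nonpolar"),
                       seed = 17)
  cx <- make_complex(spec)
  sites <- tibble::tibble(site = 1:3, x = spec$sites[, 1],
                          y = spec$sites[, 2], z = spec$sites[, 3])
  lab <- label_sites(sites, cx$waters, cx$ligand)
  expect_equal(lab$class, c("conserved", "displaced", "displaced"))
  expect_equal(lab$displaced_by[2:3], c("polar", "nonpolar"))

  shuffled <- sites[c(3, 1, 2), ]
  lab_s <- label_sites(shuffled, cx$waters, cx$ligand)
  expect_equal(lab_s$class[match(sites$site, lab_s$site)], lab$class)
  expect_identical(label_sites(sites, cx$waters, cx$ligand), lab)
})

sep_data <- function(n = 60, seed = 1) {
  # linearly separable two-class feature cloud
  withr::with_seed(seed, tibble::tibble(
    energy = c(rnorm(n / 2, -4, 0.5), rnorm(n / 2, 1, 0.5)),
    hydrophilicity = c(rnorm(n / 2, 2, 0.3), rnorm(n / 2, 0.2, 0.3)),
    lipophilicity = rnorm(n, 1, 0.3),
    label = rep(c("conserved", "displaced"), each = n / 2)
  ))
}

test_that("bagged training is deterministic and separable data is learned exactly", {
  data <- sep_data()
  m1 <- train_bagged_trees(data, n_trees = 25, seed = 11)
  m2 <- train_bagged_trees(data, n_trees = 25, seed = 11)
  expect_identical(m1$boot_idx, m2$boot_idx)
  grid <- tibble::tibble(energy = seq(-6, 3, length.out = 40),
                         hydrophilicity = seq(0, 3, length.out = 40),
                         lipophilicity = 1)
  expect_identical(predict(m1, grid), predict(m2, grid))

  # resubstitution on a separable set is perfect
  cls <- predict(m1, data, type = "class")
  expect_equal(as.character(cls), data$label)

  expect_error(train_bagged_trees(dplyr::mutate(data, label = "conserved")),
               "single class")
})

test_that("one identity-sampled tree reduces the ensemble to plain CART", {
  data <- sep_data(seed = 3)
  bag <- train_bagged_trees(data, n_trees = 1, bootstrap = FALSE, seed = 1)
  ref <- rpart::rpart(
    label ~ energy + hydrophilicity + lipophilicity, data = data,
    method = "class", parms = list(split = "gini"),
    control = rpart::rpart.control(minsplit = 15, minbucket = 5, cp = 0,
                                   maxdepth = 30, xval = 0, maxcompete = 0,
                                   maxsurrogate = 0, usesurrogate = 0)
  )
  want <- unname(predict(ref, data, type = "prob"))
  got <- unname(as.matrix(predict(bag, data, type = "prob")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("node-table traversal reproduces rpart leaf proportions across the bag", {
  data <- sep_data(n = 80, seed = 7)
  # blur the classes so trees have interesting structure
  data$energy <- data$energy + rnorm(80, 0, 1.5)
  model <- train_bagged_trees(data, n_trees = 15, seed = 2)
  newx <- sep_data(n = 40, seed = 9)

  manual <- Reduce(`+`, purrr::map(model$trees, function(tr) {
    unname(predict(tr, newx, type = "prob"))
  })) / length(model$trees)
  got <- unname(as.matrix(predict(model, newx, type = "prob")))
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("ensemble probabilities average leaf proportions and sum to one", {
  # two hand-built single-leaf trees with proportions 0.6/0.4 and 0.8/0.2
  leaf <- function(counts) list(id = 1L, var = NA_character_,
                                threshold = NA_real_, lt_left = NA,
                                counts = matrix(counts, nrow = 1))
  model <- structure(
    list(trees = NULL, nodes = list(leaf(c(3, 2)), leaf(c(4, 1))),
         boot_idx = NULL, classes = c("conserved", "displaced"),
         features = c("energy", "hydrophilicity", "lipophilicity"),
         n_trees = 2L, seed = 0L, params = list()),
    class = "bagged_trees"
  )
  x <- tibble::tibble(energy = 0, hydrophilicity = 0, lipophilicity = 0)
  p <- predict(model, x)
  expect_equal(unlist(p), c(conserved = 0.7, displaced = 0.3))

  # random inputs normalise
  data <- sep_data(seed = 5)
  m <- train_bagged_trees(data, n_trees = 20, seed = 4)
  rnd <- withr::with_seed(8, tibble::tibble(
    energy = runif(25, -6, 3), hydrophilicity = runif(25, 0, 3),
    lipophilicity = runif(25, 0, 2)
  ))
  probs <- as.matrix(predict(m, rnd))
  expect_equal(unname(rowSums(probs)), rep(1, 25), tolerance = 1e-12)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("ensemble probabilities stabilise as the bag grows", {
  data <- sep_data(n = 60, seed = 12)
  data$energy <- data$energy + rnorm(60, 0, 2)
  x <- tibble::tibble(energy = -1.5, hydrophilicity = 1.1, lipophilicity = 1)
  p_at <- function(n_trees) {
    vapply(1:12, function(s) {
      predict(train_bagged_trees(data, n_trees = n_trees, seed = 100 + s),
              x)$conserved
    }, numeric(1))
  }
  expect_lt(var(p_at(100)), var(p_at(10)))
})

test_that("JSON serialization round-trips models and predictions exactly", {
  data <- sep_data(n = 50, seed = 6)
  model <- train_bagged_trees(data, n_trees = 10, seed = 3)
  path <- tempfile(fileext = ".json")
  write_bagged_trees(model, path)
  back <- read_bagged_trees(path)

  expect_equal(back$classes, model$classes)
  expect_equal(back$n_trees, model$n_trees)
  newx <- sep_data(n = 30, seed = 8)
  expect_equal(predict(back, newx), predict(model, newx), tolerance = 1e-12)

  expect_error(read_bagged_trees(
    write_lines_tmp("{\"format\": \"something-else\"}", ext = ".json")
  ), "not a waterplace")
})

test_that("leave-protein-out CV separates well-constructed classes and not shuffled ones", {
  ds <- suppressMessages(build_classifier_dataset(n_proteins = 8, seed = 2))
  expect_equal(length(unique(ds$protein)), 8)

  cv <- leave_protein_out_cv(ds, label = "class", n_trees = 40, seed = 5)
  expect_equal(nrow(cv$folds), 8)
  expect_gt(cv$mean_accuracy, 0.9)
  expect_equal(sort(unique(cv$predictions$truth)),
               c("conserved", "displaced"))

  expect_equal(nrow(tidy(cv)), 8)
  expect_equal(glance(cv)$n_folds, 8)

  # shuffling labels collapses accuracy towards the majority-class rate
  shuf <- dplyr::mutate(ds, class = withr::with_seed(1, sample(class)))
  cv_shuf <- leave_protein_out_cv(shuf, label = "class", n_trees = 40,
                                  seed = 5)
  maj <- max(table(ds$class)) / nrow(ds)
  expect_lt(cv_shuf.acc <- cv_shuf$pooled_accuracy, cv$pooled_accuracy - 0.15)
  expect_lt(abs(cv_shuf.acc - maj), 0.15)
})

test_that("folds with no labeled waters are skipped with a warning", {
  ds <- suppressMessages(build_classifier_dataset(n_proteins = 3, seed = 4))
  ds$class[ds$protein == "prot02"] <- NA
  expect_warning(cv <- leave_protein_out_cv(ds, label = "class",
                                            n_trees = 10, seed = 1),
                 "fold skipped")
  expect_equal(nrow(cv$folds), 2)
})

test_that("confidence bins follow the stated edges and report NA when empty", {
  sure <- tibble::tibble(max_prob = rep(1, 5), correct = TRUE)
  b <- confidence_bins(sure)
  expect_equal(nrow(b), 5)
  expect_equal(b$accuracy[b$lower == 0.9], 1)
  expect_equal(b$n[b$lower == 0.5], 0)
  expect_true(is.na(b$accuracy[b$lower == 0.5]))
})

test_that("a calibrated classifier yields non-decreasing bin accuracy", {
  preds <- withr::with_seed(99, {
    p <- runif(4000, 0.5, 1)
    tibble::tibble(max_prob = p, correct = runif(4000) < p)
  })
  b <- confidence_bins(preds)
  acc <- b$accuracy[b$n > 0]
  expect_true(all(diff(acc) >= 0))
})

test_that("the two-model cascade beats chance for all four outcomes", {
  ds <- suppressMessages(build_classifier_dataset(n_proteins = 10, seed = 6))
  m_role <- train_bagged_trees(ds, label = "class", n_trees = 40, seed = 2)
  disp <- ds[ds$class == "displaced", ]
  m_disp <- train_bagged_trees(disp, label = "displaced_by", n_trees = 40,
                               seed = 3)
  out <- classify_sites(ds, m_role, m_disp)
  expect_equal(out$p_conserved + out$p_displaced, rep(1, nrow(out)),
               tolerance = 1e-9)
  hit <- out$predicted_class == ds$class4
  for (cl in unique(ds$class4)) {
    expect_gt(mean(hit[ds$class4 == cl]), 0.5)
  }
})
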