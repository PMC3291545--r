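# Validation machinery: consensus waters across replicate structures,
# true/false-positive accounting, a random-placement baseline on a
# clash-free grid, and ligand displacement-propensity profiles.

#' Binding-site box
#'
#' @param center Length-3 box centre (e.g. the ligand centroid).
#' @param side Full edge length of the cube, A (default 15).
#' @return A list of class `site_box`.
#' @export
site_box <- function(center, side = 15) {
  center <- drop(xyz_matrix(center))
  stopifnot(side > 0)
  structure(list(center = center, side = side), class = "site_box")
}

in_box <- function(points, box) {
  if (is.null(box)) return(rep(TRUE, nrow(xyz_matrix(points))))
  m <- xyz_matrix(points)
  h <- box$side / 2
  apply(abs(sweep(m, 2, box$center)), 1, max) <= h
}

#' Find consensus waters across replicate structures
#'
#' Pools the water oxygens of pre-aligned replicate structures and
#' single-linkage merges them at `radius`.  Groups holding waters from at
#' least two distinct structures are consensus sites (represented by the
#' group mean, with the number of supporting structures); the rest are
#' singletons.
#'
#' @param structures List (>= 2) of atom tibbles in a common frame.
#' @param radius Merge radius, A.
#' @param box Optional [site_box()] restricting the analysis region.
#' @return A list of class `consensus_set`: `consensus` tibble
#'   (`x`, `y`, `z`, `support`) and `singletons` tibble (`x`, `y`, `z`).
#' @export
find_consensus <- function(structures, radius = 1.0, box = NULL) {
  if (!is.list(structures) || length(structures) < 2) {
    abort("find_consensus needs at least 2 replicate structures")
  }
  waters <- imap(structures, function(s, i) {
    w <- s[s$record_kind == "water", c("x", "y", "z"), drop = FALSE]
    w$structure <- i
    w
  }) |> dplyr::bind_rows()
  if (!is.null(box) && nrow(waters) > 0) {
    waters <- waters[in_box(waters, box), , drop = FALSE]
  }
  if (nrow(waters) == 0) {
    return(structure(list(
      consensus = tibble(x = double(), y = double(), z = double(),
                         support = integer()),
      singletons = tibble(x = double(), y = double(), z = double())
    ), class = "consensus_set"))
  }
  cl <- single_linkage_cluster(waters, radius)
  grouped <- waters |>
    mutate(.cl = cl) |>
    group_by(.data$.cl) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              support = dplyr::n_distinct(.data$structure),
              .groups = "drop")
  consensus <- grouped |>
    filter(.data$support >= 2) |>
    arrange(.data$x, .data$y, .data$z) |>
    select("x", "y", "z", "support")
  singles <- grouped |>
    filter(.data$support < 2) |>
    arrange(.data$x, .data$y, .data$z) |>
    select("x", "y", "z")
  structure(list(consensus = consensus, singletons = singles),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus set: %d consensus water(s), %d singleton(s)\n",
              nrow(x$consensus), nrow(x$singletons)))
  invisible(x)
}

# greedy one-to-one matching, closest pairs first; returns matched
# distances and the matched consensus indices
greedy_match <- function(pred, ref, max_error) {
  if (nrow(pred) == 0 || nrow(ref) == 0) {
    return(list(dist = numeric(), ref_idx = integer(), pred_idx = integer()))
  }
  d <- cross_dist(pred, ref)
  cand <- which(d <= max_error, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(list(dist = numeric(), ref_idx = integer(), pred_idx = integer()))
  }
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  used_p <- logical(nrow(pred)); used_r <- logical(nrow(ref))
  dd <- numeric(); ri <- integer(); pi <- integer()
  for (j in seq_len(nrow(cand))) {
    p <- cand[j, 1]; r <- cand[j, 2]
    if (!used_p[p] && !used_r[r]) {
      used_p[p] <- TRUE; used_r[r] <- TRUE
      dd <- c(dd, d[p, r]); ri <- c(ri, r); pi <- c(pi, p)
    }
  }
  list(dist = dd, ref_idx = ri, pred_idx = pi)
}

#' Evaluate predicted sites against a consensus set
#'
#' A consensus water counts as predicted (true positive) if any prediction
#' lies within `max_error`; a prediction is a false positive if it is not
#' matched one-to-one to an experimental water -- consensus or singleton --
#' within `max_error` (greedy matching, closest pairs first, so a single
#' water flanked by two predictions yields one false positive).  Mean
#' error is computed over the greedy one-to-one prediction/consensus
#' matches.  Consensus waters (and singletons) can be pre-filtered to the
#' first hydration shell by supplying the protein atoms and a distance
#' filter.
#'
#' @param predicted Site tibble (`x`, `y`, `z`).
#' @param consensus A `consensus_set` from [find_consensus()].
#' @param max_error Maximum accepted placement error, A (1.5 or 2.0 in the
#'   standard reports).
#' @param protein Optional protein atom tibble for the hydration-shell
#'   filter.
#' @param protein_dist_filter Maximum distance of experimental waters from
#'   the protein, A (3.0 or 3.3); applied when `protein` is given.
#' @return One-row tibble: counts, percentages and mean error.
#' @export
evaluate_predictions <- function(predicted, consensus, max_error = 2.0,
                                 protein = NULL, protein_dist_filter = 3.3) {
  stopifnot(inherits(consensus, "consensus_set"))
  cw <- consensus$consensus
  sg <- consensus$singletons
  if (!is.null(protein) && nrow(protein) > 0) {
    keep_near <- function(w) {
      if (nrow(w) == 0) return(w)
      d <- apply(cross_dist(w, protein), 1, min)
      w[d <= protein_dist_filter, , drop = FALSE]
    }
    cw <- keep_near(cw)
    sg <- keep_near(sg)
  }

  n_pred <- nrow(predicted)
  tp <- 0L
  if (nrow(cw) > 0 && n_pred > 0) {
    dmin <- apply(cross_dist(cw, predicted), 1, min)
    tp <- sum(dmin <= max_error)
  }
  all_exp <- dplyr::bind_rows(cw[, c("x", "y", "z")], sg)
  fp <- 0L
  if (n_pred > 0) {
    m_all <- greedy_match(predicted, all_exp, max_error)
    fp <- n_pred - length(m_all$pred_idx)
  }
  m <- greedy_match(predicted, cw, max_error)
  tibble(
    n_consensus = nrow(cw),
    n_predicted_consensus = as.integer(tp),
    pct_consensus_predicted = if (nrow(cw) > 0) 100 * tp / nrow(cw) else NA_real_,
    n_predictions = n_pred,
    n_false_positives = as.integer(fp),
    pct_false_positives = if (n_pred > 0) 100 * fp / n_pred else NA_real_,
    mean_error = if (length(m$dist) > 0) mean(m$dist) else NA_real_,
    max_error = max_error,
    protein_dist_filter = if (is.null(protein)) NA_real_ else protein_dist_filter
  )
}

#' Random placement baseline
#'
#' Samples `n` grid nodes, uniformly without replacement, from the
#' sterically allowed volume of a binding-site box: nodes with no heavy
#' atom closer than the sum of the van der Waals radii (a clash grid
#' standing in for an affinity map).  Deterministic given `seed`.
#'
#' @param atoms Structure atom tibble (may be empty).
#' @param box A [site_box()].
#' @param n Number of random points.
#' @param spacing Grid spacing, A.
#' @param seed Integer seed.
#' @param params [score_params()] supplying the vdW radii.
#' @return Tibble of points (`x`, `y`, `z`); fewer than `n` with a warning
#'   if the allowed volume is too small.
#' @export
random_baseline <- function(atoms, box, n = 500, spacing = 1.0, seed = 1,
                            params = score_params()) {
  stopifnot(inherits(box, "site_box"))
  h <- box$side / 2
  ax <- lapply(box$center, function(c0) seq(c0 - h, c0 + h, by = spacing))
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))

  if (nrow(atoms) > 0) {
    heavy <- atoms[atoms$element != "H", , drop = FALSE]
    if (nrow(heavy) > 0) {
      rad <- vdw_radius(heavy$element, params) + params$water_radius
      d <- cross_dist(grid, heavy)
      clash <- d < matrix(rad, nrow(grid), length(rad), byrow = TRUE)
      grid <- grid[!apply(clash, 1, any), , drop = FALSE]
    }
  }
  if (nrow(grid) < n) {
    warn(sprintf("only %d clash-free grid nodes available (requested %d)",
                 nrow(grid), n))
    pick <- seq_len(nrow(grid))
  } else {
    pick <- withr::with_seed(seed, sample.int(nrow(grid), n))
  }
  as_tibble(grid[pick, , drop = FALSE])
}

#' Minimum distances from points to reference waters
#'
#' @param points Tibble/matrix of positions (e.g. predicted sites or
#'   random baseline points).
#' @param reference Tibble/matrix of reference water positions (must be
#'   non-empty).
#' @return Tibble with one row per point: `min_dist` plus the input
#'   coordinates.  Quartiles for box-plot summaries are available via
#'   `quantile(out$min_dist)`.
#' @export
error_distribution <- function(points, reference) {
  ref <- xyz_matrix(reference)
  if (nrow(ref) == 0) abort("reference water set is empty")
  pts <- xyz_matrix(points)
  d <- apply(cross_dist(pts, ref), 1, min)
  out <- as_tibble(pts)
  out$min_dist <- d
  out
}

#' Ligand displacement-propensity profile
#'
#' For each ligand atom class (hydrogen-bond donor, acceptor, aromatic
#' carbon, non-aromatic carbon) and each element (O, N, C), the fraction
#' of that class's atoms whose distance to the nearest predicted water
#' site falls within each cumulative distance cutoff.  Fractions are
#' normalised within class, so curves are per-atom displacement
#' propensities and classes of very different abundance remain
#' comparable.  Classes with no atoms are omitted with a note.
#'
#' @param sites Predicted (displaced) site tibble (`x`, `y`, `z`).
#' @param ligand Ligand atom tibble with roles assigned.
#' @param cutoffs Increasing distance cutoffs, A.
#' @return Long tibble: `group_type` (`role`/`element`), `group`,
#'   `cutoff`, `n_atoms`, `probability`.
#' @export
propensity_profile <- function(sites, ligand,
                               cutoffs = seq(0.5, 4, by = 0.5)) {
  stopifnot(nrow(sites) > 0, nrow(ligand) > 0,
            all(c("is_donor", "is_acceptor", "is_carbon") %in% names(ligand)))
  dmin <- apply(cross_dist(ligand, sites), 1, min)
  arom <- if ("is_aromatic" %in% names(ligand)) ligand$is_aromatic else
    rep(FALSE, nrow(ligand))
  classes <- list(
    role = list(
      donor = ligand$is_donor,
      acceptor = ligand$is_acceptor,
      carbon_aromatic = ligand$is_carbon & arom,
      carbon_nonaromatic = ligand$is_carbon & !arom
    ),
    element = list(
      O = ligand$element == "O",
      N = ligand$element == "N",
      C = ligand$element == "C"
    )
  )
  rows <- list()
  for (ty in names(classes)) {
    for (g in names(classes[[ty]])) {
      sel <- classes[[ty]][[g]]
      if (!any(sel)) {
        inform(sprintf("propensity_profile: no %s atoms; class omitted", g))
        next
      }
      rows[[length(rows) + 1]] <- tibble(
        group_type = ty, group = g, cutoff = cutoffs,
        n_atoms = sum(sel),
        probability = vapply(cutoffs,
                             function(ct) mean(dmin[sel] <= ct), numeric(1))
      )
    }
  }
  dplyr::bind_rows(rows)
}
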