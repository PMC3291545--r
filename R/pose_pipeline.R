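# From a raw ensemble of docked water poses to predicted hydration sites.
#
# The pipeline is: (1) drop poses scoring worse than the energy cutoff,
# (2) single-linkage cluster the surviving oxygen positions at a tight
# radius to collapse near-duplicates, (3) single-linkage cluster the
# resulting cluster means at a wider radius, and report each final
# cluster's mean of means as one predicted site.  Everything downstream of
# the docking engine is deterministic.

#' Clustering parameters for site prediction
#'
#' Defaults are the validated protocol values: poses scoring above
#' -0.6 kcal/mol are discarded (docking scores are negative-favourable),
#' the first clustering round merges poses within 0.5 A to remove
#' overlapping duplicates, and the second round merges the round-one means
#' within 1.6 A -- about the van der Waals radius of a water molecule.
#'
#' @param score_cutoff Maximum (least favourable) accepted pose score,
#'   kcal/mol.
#' @param round1_cutoff First-round single-linkage distance cutoff, A.
#' @param round2_cutoff Second-round cutoff, A; must exceed `round1_cutoff`.
#' @param runs_expected Number of independent docking runs pooled.
#' @param per_run_cap Maximum modes the engine emits per run.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(score_cutoff = -0.6, round1_cutoff = 0.5,
                           round2_cutoff = 1.6, runs_expected = 3,
                           per_run_cap = 20) {
  stopifnot(round1_cutoff > 0, round2_cutoff > 0,
            round1_cutoff < round2_cutoff,
            runs_expected >= 1, per_run_cap >= 1)
  structure(
    list(score_cutoff = score_cutoff, round1_cutoff = round1_cutoff,
         round2_cutoff = round2_cutoff, runs_expected = runs_expected,
         per_run_cap = per_run_cap),
    class = "cluster_params"
  )
}

#' Filter docked poses by score
#'
#' Keeps poses whose score is at least as favourable as the cutoff
#' (`score <= cutoff`; docking scores are negative-favourable).  Order is
#' preserved and an empty input returns an empty tibble.
#'
#' @param poses Pose tibble from [read_pose_ensemble()].
#' @param cutoff Score cutoff, kcal/mol.
#' @return The retained poses.
#' @export
filter_poses <- function(poses, cutoff = -0.6) {
  stopifnot(is.data.frame(poses), "score" %in% names(poses))
  poses[poses$score <= cutoff, , drop = FALSE]
}

#' Single-linkage clustering at a distance threshold
#'
#' Two points share a cluster iff they are connected by a chain of
#' pairwise distances `<= cutoff` (connected components of the
#' distance-threshold graph).  Points at exactly the cutoff distance
#' merge.
#'
#' @param points Tibble with `x`, `y`, `z` columns, a 3-column matrix, or
#'   a single length-3 vector.
#' @param cutoff Distance threshold, A.
#' @return Integer cluster membership, one entry per point.
#' @export
single_linkage_cluster <- function(points, cutoff) {
  m <- xyz_matrix(points)
  if (!all(is.finite(m))) abort("non-finite coordinates in clustering input")
  stopifnot(nrow(m) >= 1, cutoff > 0)
  if (nrow(m) == 1) return(1L)
  hc <- hclust(dist(m), method = "single")
  as.integer(cutree(hc, h = cutoff))
}

#' Predict hydration sites from a pose ensemble
#'
#' Applies the score filter (optional) and the two-round single-linkage
#' procedure.  Round one clusters pose positions at `round1_cutoff` and
#' replaces each cluster with its mean; round two clusters those means at
#' `round2_cutoff`.  A site's position is the unweighted mean of its
#' round-two members (a mean of round-one means), and `n_members` counts
#' all contributing poses.  Sites are ordered by `n_members` (descending),
#' then best member score, then position.
#'
#' @param poses Pose tibble (`x`, `y`, `z`, `score`).
#' @param params A [cluster_params()] object.
#' @param apply_filter Apply the score filter first (default); set to
#'   `FALSE` if the poses are already filtered.
#' @param position `"mean_of_means"` (default) reports each site at the
#'   unweighted mean of its round-one cluster means, treating the merged
#'   clusters as the round-two objects; `"pose_weighted"` reports the
#'   plain mean over all contributing poses instead.
#' @return A site tibble: `site`, `x`, `y`, `z`, `n_members`,
#'   `best_score`, and a `member_scores` list-column.
#' @export
#' @examples
#' poses <- tibble::tibble(
#'   x = c(0, 0.1, 4, 4.1), y = 0, z = 0,
#'   score = c(-1.5, -1.4, -1.2, -1.1)
#' )
#' predict_sites(poses)
predict_sites <- function(poses, params = cluster_params(),
                          apply_filter = TRUE,
                          position = c("mean_of_means", "pose_weighted")) {
  position <- arg_match(position)
  stopifnot(inherits(params, "cluster_params"))
  if (apply_filter) poses <- filter_poses(poses, params$score_cutoff)
  if (nrow(poses) == 0) {
    inform("predict_sites: no poses survive the score filter")
    return(tibble(site = integer(), x = double(), y = double(), z = double(),
                  n_members = integer(), best_score = double(),
                  member_scores = list()))
  }

  r1 <- single_linkage_cluster(poses, params$round1_cutoff)
  means1 <- poses |>
    mutate(.cl1 = r1) |>
    group_by(.data$.cl1) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              n_poses = dplyr::n(),
              scores = list(.data$score), .groups = "drop")

  r2 <- single_linkage_cluster(means1, params$round2_cutoff)
  means1$.wt <- if (position == "pose_weighted") means1$n_poses else
    rep(1, nrow(means1))
  sites <- means1 |>
    mutate(.cl2 = r2) |>
    group_by(.data$.cl2) |>
    summarise(
      x = stats::weighted.mean(.data$x, .data$.wt),
      y = stats::weighted.mean(.data$y, .data$.wt),
      z = stats::weighted.mean(.data$z, .data$.wt),
      n_members = as.integer(sum(.data$n_poses)),
      member_scores = list(unlist(.data$scores)),
      .groups = "drop"
    ) |>
    mutate(best_score = map_dbl(.data$member_scores, min)) |>
    arrange(desc(.data$n_members), .data$best_score,
            .data$x, .data$y, .data$z) |>
    mutate(site = row_number()) |>
    select("site", "x", "y", "z", "n_members", "best_score", "member_scores")
  sites
}
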