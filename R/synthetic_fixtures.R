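# Synthetic test articles: toy binding pockets with planted water sites,
# saturated docking-run ensembles, replicate "crystal" structures and
# overlaid ligands.  Fixtures are geometric constructions, not realistic
# protein folds; every generator is reproducible from (spec, seed).
#
# Noise conventions: jitter vectors are isotropic Gaussian displacements
# with their norm capped (3 sigma for poses, 1.5 sigma for replicate
# waters) so that planted ground truth stays unambiguous at the pipeline's
# merge radii -- a pose can never wander into another site's cluster, and
# replicate copies of one consensus water can never drift past the 1 A
# consensus radius.

#' Specification of a synthetic fixture
#'
#' @param n_sites Number of planted hydration sites.
#' @param sites Optional matrix/tibble of site positions (rows, A);
#'   default lays sites on a 5 A grid.
#' @param site_env Per-site pocket chemistry: `"polar"` (2 acceptors +
#'   1 donor + 1 carbon), `"mixed"` (1 acceptor + 2 carbons) or
#'   `"nonpolar"` (4 carbons).  Recycled.
#' @param overlap_plan Per-site fate when the ligand is overlaid:
#'   `"conserved"` (crystal water survives), `"polar"` (displaced by a
#'   ligand oxygen), `"nonpolar"` (displaced by a ligand carbon) or
#'   `"none"` (site matches nothing).  Recycled.
#' @param pose_sigma Docked-pose jitter about the planted site, A.
#' @param poses_per_site Planted poses per site per run.
#' @param planted_score_mean,planted_score_sd Score distribution of
#'   planted poses, kcal/mol (favourable side of the -0.6 filter).
#' @param decoy_score_mean,decoy_score_sd Score distribution of decoy
#'   poses (straddling the filter so it is exercised).
#' @param n_runs,per_run_cap Docking-run semantics: number of pooled runs
#'   and the engine's per-run mode cap.
#' @param n_replicates Replicate "crystal" structures to emit.
#' @param replicate_sigma Water-position jitter between replicates, A.
#' @param n_singletons Waters planted in exactly one replicate.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_sites = 3, sites = NULL,
                         site_env = c("polar", "mixed", "nonpolar"),
                         overlap_plan = "conserved",
                         pose_sigma = 0.3, poses_per_site = 5,
                         planted_score_mean = -1.5, planted_score_sd = 0.3,
                         decoy_score_mean = -0.3, decoy_score_sd = 0.2,
                         n_runs = 3, per_run_cap = 20,
                         n_replicates = 3, replicate_sigma = 0.3,
                         n_singletons = 0, seed = 1) {
  stopifnot(n_sites >= 1, pose_sigma >= 0, replicate_sigma >= 0,
            n_runs >= 1, per_run_cap >= 1, poses_per_site >= 1,
            n_replicates >= 1, n_singletons >= 0)
  if (is.null(sites)) {
    g <- expand.grid(x = seq(0, 20, by = 5), y = seq(0, 20, by = 5),
                     z = seq(0, 20, by = 5))
    g <- g[order(g$z, g$y, g$x), ]
    sites <- as.matrix(g[seq_len(n_sites), ])
  } else {
    sites <- xyz_matrix(sites)
    n_sites <- nrow(sites)
  }
  dimnames(sites) <- list(NULL, c("x", "y", "z"))
  structure(
    list(n_sites = n_sites, sites = sites,
         site_env = rep_len(site_env, n_sites),
         overlap_plan = rep_len(overlap_plan, n_sites),
         pose_sigma = pose_sigma, poses_per_site = poses_per_site,
         planted_score_mean = planted_score_mean,
         planted_score_sd = planted_score_sd,
         decoy_score_mean = decoy_score_mean,
         decoy_score_sd = decoy_score_sd,
         n_runs = n_runs, per_run_cap = per_run_cap,
         n_replicates = n_replicates, replicate_sigma = replicate_sigma,
         n_singletons = n_singletons, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# isotropic gaussian displacements truncated to norm <= cap (rejection
# sampling, so no probability mass piles up at the cap shell)
capped_noise <- function(n, sigma, cap) {
  if (sigma == 0 || n == 0) return(matrix(0, n, 3))
  m <- matrix(rnorm(3 * n, sd = sigma), n, 3)
  bad <- sqrt(rowSums(m^2)) > cap
  while (any(bad)) {
    m[bad, ] <- matrix(rnorm(3 * sum(bad), sd = sigma), sum(bad), 3)
    bad <- sqrt(rowSums(m^2)) > cap
  }
  m
}

# random unit vectors with pairwise angular separation > 40 degrees
spread_directions <- function(k, max_tries = 500) {
  dirs <- matrix(NA_real_, k, 3)
  got <- 0
  for (try in seq_len(max_tries)) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    if (got == 0 || all(dirs[seq_len(got), , drop = FALSE] %*% v < 0.766)) {
      got <- got + 1
      dirs[got, ] <- v
      if (got == k) return(dirs)
    }
  }
  abort("infeasible pocket geometry: could not spread atoms around a site")
}

env_composition <- function(env) {
  switch(env,
    polar = list(acceptor = 2, donor = 1, carbon = 1),
    mixed = list(acceptor = 1, donor = 0, carbon = 2),
    nonpolar = list(acceptor = 0, donor = 0, carbon = 4),
    abort(paste0("unknown site environment: ", env))
  )
}

#' Build a synthetic pocket around the planted sites
#'
#' Pseudo-protein atoms are placed at hydrogen-bonding range (2.8--3.0 A)
#' from each planted site for the polar contingent and at van der Waals
#' contact range (3.4--3.9 A) for the carbon lining, using standard
#' residue atom types so role and propensity lookups resolve naturally
#' (acceptors as carboxylate oxygens, donors as lysine amines, carbons as
#' alanine side chains).
#'
#' @param spec A [fixture_spec()].
#' @return An atom tibble with roles assigned.
#' @export
make_pocket <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    rows <- list()
    serial <- 0L
    for (i in seq_len(spec$n_sites)) {
      comp <- env_composition(spec$site_env[[i]])
      k <- comp$acceptor + comp$donor + comp$carbon
      other <- spec$sites[-i, , drop = FALSE]
      types <- c(rep("acceptor", comp$acceptor), rep("donor", comp$donor),
                 rep("carbon", comp$carbon))
      # resample directions until no atom encroaches on another site's
      # scoring environment, so each site keeps its requested chemistry
      for (try in seq_len(200)) {
        dirs <- spread_directions(k)
        rr <- ifelse(types == "carbon", runif(k, 3.4, 3.9), runif(k, 2.8, 3.0))
        cand <- spec$sites[rep(i, k), , drop = FALSE] + rr * dirs
        if (nrow(other) == 0 || min(cross_dist(cand, other)) >= 4.0) break
        if (try == 200) abort("infeasible pocket geometry: sites too close")
      }
      for (j in seq_len(k)) {
        pos <- as.numeric(cand[j, ])
        serial <- serial + 1L
        rows[[serial]] <- tibble(
          serial = serial,
          name = switch(types[j], acceptor = "OD1", donor = "NZ",
                        carbon = "CB"),
          resid = switch(types[j], acceptor = "ASP", donor = "LYS",
                         carbon = "ALA"),
          chain = "A", resno = serial,
          x = pos[1], y = pos[2], z = pos[3],
          element = switch(types[j], acceptor = "O", donor = "N",
                           carbon = "C"),
          record_kind = "protein"
        )
      }
    }
    atoms <- dplyr::bind_rows(rows)
    attr(atoms, "structure_id") <- sprintf("synthetic-pocket-seed%d", spec$seed)
    assign_roles(atoms, quiet = TRUE)
  })
}

#' Generate the pooled docked-pose ensemble for a fixture
#'
#' Each run holds `poses_per_site` poses jittered about every planted site
#' with favourable scores, topped up to the per-run cap with decoy poses
#' placed at least 3 A from any site and scored around the filter cutoff.
#' Poses within a run are ordered by score, as a docking engine would
#' emit them.
#'
#' @param spec A [fixture_spec()].
#' @return A pose tibble (`x`, `y`, `z`, `score`, `run`, `mode`).
#' @export
make_poses <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_sites * spec$poses_per_site > spec$per_run_cap) {
    abort("poses_per_site * n_sites exceeds the per-run mode cap")
  }
  lo <- apply(spec$sites, 2, min) - 5
  hi <- apply(spec$sites, 2, max) + 5
  runs <- list()
  for (r in seq_len(spec$n_runs)) {
    runs[[r]] <- withr::with_seed(spec$seed + 101L * r, {
      planted <- map(seq_len(spec$n_sites), function(i) {
        np <- spec$poses_per_site
        jit <- capped_noise(np, spec$pose_sigma, 3 * spec$pose_sigma)
        tibble(
          x = spec$sites[i, 1] + jit[, 1],
          y = spec$sites[i, 2] + jit[, 2],
          z = spec$sites[i, 3] + jit[, 3],
          score = rnorm(np, spec$planted_score_mean, spec$planted_score_sd)
        )
      }) |> dplyr::bind_rows()
      n_decoy <- spec$per_run_cap - nrow(planted)
      decoys <- tibble(x = double(), y = double(), z = double(),
                       score = double())
      if (n_decoy > 0) {
        pts <- matrix(NA_real_, 0, 3)
        while (nrow(pts) < n_decoy) {
          cand <- cbind(runif(4 * n_decoy, lo[1], hi[1]),
                        runif(4 * n_decoy, lo[2], hi[2]),
                        runif(4 * n_decoy, lo[3], hi[3]))
          ok <- apply(cross_dist(cand, spec$sites), 1, min) >= 3
          pts <- rbind(pts, cand[ok, , drop = FALSE])
        }
        pts <- pts[seq_len(n_decoy), , drop = FALSE]
        decoys <- tibble(
          x = pts[, 1], y = pts[, 2], z = pts[, 3],
          score = rnorm(n_decoy, spec$decoy_score_mean, spec$decoy_score_sd)
        )
      }
      out <- dplyr::bind_rows(planted, decoys) |> arrange(.data$score)
      out$run <- r
      out$mode <- seq_len(nrow(out))
      out
    })
  }
  dplyr::bind_rows(runs)
}

#' Write a fixture's pose ensemble as per-run multi-model PDBQT files
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, one per run.
#' @export
make_pose_runs <- function(spec, dir = tempfile("poses")) {
  poses <- make_poses(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(spec$n_runs)
  for (r in seq_len(spec$n_runs)) {
    p <- poses[poses$run == r, , drop = FALSE]
    lines <- unlist(map(seq_len(nrow(p)), function(m) {
      c(sprintf("MODEL %d", m),
        sprintf("REMARK VINA RESULT:    %8.3f      0.000      0.000",
                p$score[m]),
        sprintf("HETATM    1  O   HOH A   1    %8.3f%8.3f%8.3f  1.00  0.00           O",
                p$x[m], p$y[m], p$z[m]),
        "ENDMDL")
    }))
    paths[r] <- file.path(dir, sprintf("run%d.pdbqt", r))
    writeLines(lines, paths[r])
  }
  paths
}

#' Generate replicate "crystal" structures
#'
#' Every planted site appears as a water in all replicates (jittered by
#' `replicate_sigma`, norm-capped so replicate copies always stay within
#' the 1 A consensus radius of each other); singleton waters appear in
#' exactly one replicate, offset 2.5 A from a site so they can never be
#' mistaken for consensus.
#'
#' @param spec A [fixture_spec()].
#' @return List of `n_replicates` atom tibbles (pocket plus waters).
#' @export
make_replicates <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_replicates < 2) {
    abort("make_replicates needs n_replicates >= 2 for a consensus analysis")
  }
  pocket <- make_pocket(spec)
  cap <- min(1.5 * spec$replicate_sigma, 0.45)
  offs <- diag(3) * 2.5
  singles <- NULL
  if (spec$n_singletons > 0) {
    singles <- t(vapply(seq_len(spec$n_singletons), function(j) {
      spec$sites[(j - 1) %% spec$n_sites + 1, ] +
        offs[(j - 1) %/% spec$n_sites %% 3 + 1, ]
    }, numeric(3)))
  }
  withr::with_seed(spec$seed + 7777L, {
    map(seq_len(spec$n_replicates), function(k) {
      jit <- capped_noise(spec$n_sites, spec$replicate_sigma, cap)
      w <- spec$sites + jit
      if (!is.null(singles)) {
        mine <- which((seq_len(spec$n_singletons) - 1) %% spec$n_replicates + 1 == k)
        if (length(mine) > 0) w <- rbind(w, singles[mine, , drop = FALSE])
      }
      waters <- tibble(
        serial = max(pocket$serial) + seq_len(nrow(w)),
        name = "O", resid = "HOH", chain = "A",
        resno = max(pocket$resno) + seq_len(nrow(w)),
        x = w[, 1], y = w[, 2], z = w[, 3],
        element = "O", record_kind = "water"
      )
      rep_k <- dplyr::bind_rows(pocket, waters)
      attr(rep_k, "structure_id") <- sprintf("replicate%d", k)
      rep_k
    })
  })
}

#' Generate a holo complex for the retrospective displacement protocol
#'
#' Overlays a minimal ligand onto the planted sites according to the
#' fixture's overlap plan: polar-overlap sites receive a ligand oxygen,
#' non-polar-overlap sites a ligand carbon, conserved sites keep a crystal
#' water, and `"none"` sites are left empty.  Ligand atoms and retained
#' waters sit within 0.3 A of their site.
#'
#' @param spec A [fixture_spec()].
#' @return List: `apo` (pocket atom tibble), `ligand` (atom tibble with
#'   roles), `waters` (tibble of crystal-water positions).
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  pocket <- make_pocket(spec)
  withr::with_seed(spec$seed + 4242L, {
    lig <- list(); wat <- list()
    for (i in seq_len(spec$n_sites)) {
      jit <- drop(capped_noise(1, 0.15, 0.3))
      pos <- as.numeric(spec$sites[i, ]) + jit
      plan <- spec$overlap_plan[[i]]
      if (plan == "conserved") {
        wat[[length(wat) + 1]] <- tibble(x = pos[1], y = pos[2], z = pos[3])
      } else if (plan %in% c("polar", "nonpolar")) {
        el <- if (plan == "polar") "O" else "C"
        lig[[length(lig) + 1]] <- tibble(
          serial = length(lig) + 1L,
          name = paste0(el, length(lig) + 1), resid = "LIG", chain = "A",
          resno = 900L, x = pos[1], y = pos[2], z = pos[3],
          element = el, record_kind = "ligand",
          is_donor = FALSE, is_acceptor = el == "O",
          is_carbon = el == "C", is_aromatic = FALSE, is_polar_h = FALSE
        )
      } else if (plan != "none") {
        abort(paste0("unknown overlap plan entry: ", plan))
      }
    }
    list(
      apo = pocket,
      ligand = dplyr::bind_rows(lig),
      waters = dplyr::bind_rows(wat)
    )
  })
}

#' Run the whole pipeline over a set of synthetic proteins
#'
#' For each synthetic "protein": build a pocket whose per-site chemistry
#' matches its planned fate (conserved sites in polar pockets, polar
#' displacements in mixed pockets, non-polar displacements in carbon-lined
#' pockets), generate and cluster a saturated pose ensemble, score the
#' predicted sites against the pocket, and label them retrospectively
#' against the overlaid complex.  The result is a labeled feature table
#' ready for [train_bagged_trees()] / [leave_protein_out_cv()].
#'
#' @param n_proteins Number of synthetic proteins.
#' @param seed Integer seed.
#' @param sites_per_protein Planted sites per protein (multiple of 3:
#'   equal thirds conserved / polar-displaced / nonpolar-displaced).
#' @return Tibble: `protein`, the three descriptors (`energy`,
#'   `hydrophilicity`, `lipophilicity`, plus `hbond`), `class`
#'   (conserved/displaced), `class4` (conserved/displaced_polar/
#'   displaced_nonpolar) and `displaced_by`.  Ambiguous sites are dropped.
#' @export
build_classifier_dataset <- function(n_proteins = 20, seed = 1,
                                     sites_per_protein = 6) {
  out <- list()
  env_of <- c(conserved = "polar", polar = "mixed", nonpolar = "nonpolar")
  plan <- rep_len(c("conserved", "polar", "nonpolar"), sites_per_protein)
  for (p in seq_len(n_proteins)) {
    spec <- fixture_spec(
      n_sites = sites_per_protein,
      site_env = unname(env_of[plan]),
      overlap_plan = plan,
      poses_per_site = 3,
      seed = seed * 1000L + p
    )
    pocket <- make_pocket(spec)
    sites <- predict_sites(make_poses(spec)) |>
      score_sites(pocket)
    cx <- make_complex(spec)
    lab <- label_sites(sites, cx$waters, cx$ligand)
    dat <- dplyr::left_join(sites, lab, by = "site") |>
      filter(.data$class != "ambiguous") |>
      mutate(
        protein = sprintf("prot%02d", p),
        class4 = ifelse(.data$class == "conserved", "conserved",
                        paste0("displaced_", .data$displaced_by))
      ) |>
      select("protein", "hbond", "energy", "hydrophilicity",
             "lipophilicity", "class", "class4", "displaced_by")
    out[[p]] <- dat
  }
  dplyr::bind_rows(out)
}

#' Simulate a term matrix for model-mining studies
#'
#' Emulates a water binding-energy data set: `n` waters in `n_groups`
#' conserved-water groups, the full 8-term library as candidate
#' predictors, and a response generated from a known linear truth plus
#' Gaussian noise.  Defaults mirror the published study conditions: 54
#' waters, 11 groups, a single hydrogen-bond truth of slope -2.6 with
#' intercept 1.8, and 1.5 kcal/mol noise.
#'
#' @param n Rows (waters).
#' @param n_groups Conserved-water groups for leave-group-out CV.
#' @param truth Named coefficients of the generating model; names must be
#'   `"(Intercept)"` or term names.
#' @param sigma Noise standard deviation, kcal/mol.
#' @param terms Term library.
#' @param seed Integer seed.
#' @return A term-matrix tibble with columns `group`, the terms, and the
#'   response `dg`.
#' @export
simulate_term_matrix <- function(n = 54, n_groups = 11,
                                 truth = c(`(Intercept)` = 1.8,
                                           vina_hbond = -2.6),
                                 sigma = 1.5,
                                 terms = default_term_library(), seed = 1) {
  stopifnot(n_groups >= 2, n > n_groups)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(terms)), n, length(terms),
                dimnames = list(NULL, terms))
    # the hydrogen-bond term is a non-negative count-like quantity
    if ("vina_hbond" %in% terms) X[, "vina_hbond"] <- runif(n, 0, 3)
    mu <- rep(truth[["(Intercept)"]] %||% 0, n)
    for (tm in setdiff(names(truth), "(Intercept)")) {
      mu <- mu + truth[[tm]] * X[, tm]
    }
    tibble(group = rep_len(seq_len(n_groups), n)) |>
      dplyr::bind_cols(as_tibble(X)) |>
      mutate(dg = mu + rnorm(n, 0, sigma))
  })
}
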