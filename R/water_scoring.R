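# Per-site descriptors: hydrogen-bond term, refit water energy, and the
# heuristic hydrophilicity / lipophilicity environment scores.
#
# The hydrogen-bond term follows the empirical docking convention: each
# donor/acceptor partner contributes a value that ramps linearly from 1
# (surface distance <= -0.7 A, i.e. slightly interpenetrating van der
# Waals surfaces) to 0 (surfaces touching), where surface distance is
# r - (R_water + R_partner).  The water energy is an affine map of the
# summed term, refit against calculated water binding free energies:
# E = 1.77 - 2.58 * hbond (kcal/mol).  Hydrophilicity is the
# exponentially distance-weighted sum of per-atom hydration propensities
# within 4 A; lipophilicity uses the same form with carbon propensity 1
# and 0 otherwise.

#' Scoring parameters
#'
#' @param env_cutoff Environment radius for the propensity sums, A.
#' @param d0 Distance scale of the exponential weight, A.
#' @param ramp_full Surface distance at and below which a hydrogen-bond
#'   pair contributes its full value of 1, A.
#' @param ramp_zero Surface distance at and above which the contribution
#'   is 0, A.  Must exceed `ramp_full`.
#' @param vdw_radii Named vector of per-element van der Waals radii, A.
#' @param water_radius Radius used for the water oxygen; defaults to the
#'   oxygen entry of `vdw_radii`.
#' @param weight_fun Radial weight for the environment scores; defaults to
#'   `exp(-r / d0)`.  Injectable so alternative decays can be swapped in
#'   without touching callers.
#' @return A list of class `score_params`.
#' @export
score_params <- function(env_cutoff = 4.0, d0 = 1.0,
                         ramp_full = -0.7, ramp_zero = 0.0,
                         vdw_radii = default_vdw_radii(),
                         water_radius = NULL,
                         weight_fun = NULL) {
  stopifnot(env_cutoff > 0, d0 > 0, ramp_full < ramp_zero)
  structure(
    list(env_cutoff = env_cutoff, d0 = d0,
         ramp_full = ramp_full, ramp_zero = ramp_zero,
         vdw_radii = vdw_radii,
         water_radius = water_radius %||% unname(vdw_radii[["O"]]),
         weight_fun = weight_fun %||% function(r, d0) exp(-r / d0)),
    class = "score_params"
  )
}

#' Default van der Waals radii (A) per element
#'
#' Values follow the empirical docking scoring convention the hydrogen-bond
#' ramp was designed around; metals share a single small radius.
#'
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
    F = 1.5, CL = 1.8, BR = 2.0, I = 2.2, H = 1.0,
    `NA` = 1.2, K = 1.2, MG = 1.2, CA = 1.2, ZN = 1.2,
    MN = 1.2, FE = 1.2, CU = 1.2, NI = 1.2, CO = 1.2, CD = 1.2)
}

#' Refit water energy model
#'
#' Affine map from the summed hydrogen-bond term to a water binding energy
#' in kcal/mol.  The default weights are the refit of the docking
#' hydrogen-bond term against calculated water binding free energies:
#' intercept 1.77 kcal/mol, slope -2.58 kcal/mol per unit term.
#'
#' @param intercept Intercept, kcal/mol.
#' @param hbond_weight Weight of the hydrogen-bond term, kcal/mol.
#' @return A list of class `energy_model`.
#' @export
energy_model <- function(intercept = 1.77, hbond_weight = -2.58) {
  stopifnot(is.finite(intercept), is.finite(hbond_weight))
  structure(list(intercept = intercept, hbond_weight = hbond_weight),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("water energy model: E = %.2f %+.2f * hbond  (kcal/mol)\n",
              x$intercept, x$hbond_weight))
  invisible(x)
}

vdw_radius <- function(element, params) {
  r <- params$vdw_radii[element]
  if (anyNA(r)) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unique(element[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

#' Hydrogen-bond term of a water position
#'
#' Sum over donor/acceptor partner atoms of a linear ramp on the surface
#' distance d = r - (R_water + R_partner): 1 at `d <= ramp_full`, 0 at
#' `d >= ramp_zero`, linear in between.  The water is treated as both
#' donor and acceptor, so every flagged partner counts.
#'
#' @param water Water oxygen position: length-3 vector or 1-row tibble.
#' @param atoms Atom tibble with roles assigned ([assign_roles()]).
#' @param params A [score_params()] object.
#' @param include_waters Count other water molecules as partners (default
#'   `FALSE`: sites are scored against the stripped receptor).
#' @return Dimensionless sum, `>= 0`.
#' @export
hbond_term <- function(water, atoms, params = score_params(),
                       include_waters = FALSE) {
  stopifnot(all(c("is_donor", "is_acceptor") %in% names(atoms)))
  partners <- atoms[(atoms$is_donor | atoms$is_acceptor) &
                      (include_waters | atoms$record_kind != "water"), ,
                    drop = FALSE]
  if (nrow(partners) == 0) return(0)
  r <- drop(cross_dist(water, partners))
  d_surf <- r - (params$water_radius + vdw_radius(partners$element, params))
  val <- (params$ramp_zero - d_surf) / (params$ramp_zero - params$ramp_full)
  sum(pmin(pmax(val, 0), 1))
}

#' Water energy from the hydrogen-bond term
#'
#' @param hbond_sum Summed hydrogen-bond term, dimensionless, `>= 0`.
#' @param model An [energy_model()].
#' @return Energy in kcal/mol.
#' @export
water_energy <- function(hbond_sum, model = energy_model()) {
  stopifnot(all(hbond_sum >= 0))
  model$intercept + model$hbond_weight * hbond_sum
}

#' Read a hydration-propensity table
#'
#' Tab-separated columns `residue`, `atom`, `h`; rows with `residue == "*"`
#' are element-class fallbacks.  The shipped default is a synthetic
#' stand-in on the usual `[0, 1]` propensity scale (see the file header);
#' supply measured per-atom-type values for production work.
#'
#' @param path Optional path to a propensity TSV.
#' @return A tibble with attribute `max_h` (the table maximum, used for
#'   ions).
#' @export
read_propensity_table <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "hydration_propensity_synthetic.tsv",
                package = "waterplace")
  tab <- as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                              stringsAsFactors = FALSE))
  stopifnot(all(c("residue", "atom", "h") %in% names(tab)), all(tab$h >= 0))
  attr(tab, "max_h") <- max(tab$h)
  tab
}

# resolve the hydration propensity of every atom in the environment:
# protein atoms by (residue, atom name) then element fallback; cofactor
# atoms by the most similar protein atom (element-class lookup); ions get
# the table maximum
resolve_propensity <- function(atoms, table) {
  max_h <- attr(table, "max_h") %||% max(table$h)
  specific <- table[table$residue != "*", , drop = FALSE]
  fallback <- table[table$residue == "*", , drop = FALSE]

  h <- rep(NA_real_, nrow(atoms))
  hit <- match(paste(atoms$resid, atoms$name),
               paste(specific$residue, specific$atom))
  h[!is.na(hit)] <- specific$h[hit[!is.na(hit)]]

  need <- is.na(h)
  fhit <- match(atoms$element[need], fallback$atom)
  h[need] <- fallback$h[fhit]

  h[atoms$record_kind == "ion"] <- max_h
  if (anyNA(h)) {
    bad <- atoms[is.na(h), , drop = FALSE]
    abort(paste0("no hydration propensity for atom(s): ",
                 paste(unique(paste(bad$resid, bad$name)), collapse = ", ")))
  }
  h
}

env_atoms <- function(water, atoms, params) {
  env <- atoms[atoms$record_kind %in% c("protein", "cofactor", "ion"), ,
               drop = FALSE]
  if (nrow(env) == 0) return(list(atoms = env, r = numeric()))
  r <- drop(cross_dist(water, env))
  keep <- r <= params$env_cutoff
  list(atoms = env[keep, , drop = FALSE], r = r[keep])
}

#' Hydrophilicity of a water environment
#'
#' Distance-weighted sum of per-atom hydration propensities over all
#' protein/cofactor/ion atoms within the environment cutoff:
#' sum of h_i * exp(-r_i / d0).  Ligand and water atoms are excluded.
#'
#' @inheritParams hbond_term
#' @param table Propensity table, see [read_propensity_table()].
#' @return Dimensionless score, `>= 0`.
#' @export
hydrophilicity <- function(water, atoms, table = read_propensity_table(),
                           params = score_params()) {
  e <- env_atoms(water, atoms, params)
  if (nrow(e$atoms) == 0) return(0)
  h <- resolve_propensity(e$atoms, table)
  sum(h * params$weight_fun(e$r, params$d0))
}

#' Lipophilicity of a water environment
#'
#' Same functional form as [hydrophilicity()] with carbon propensity 1 and
#' every other atom type 0.
#'
#' @inheritParams hydrophilicity
#' @return Dimensionless score, `>= 0`.
#' @export
lipophilicity <- function(water, atoms, table = read_propensity_table(),
                          params = score_params()) {
  e <- env_atoms(water, atoms, params)
  if (nrow(e$atoms) == 0) return(0)
  l <- as.numeric(e$atoms$element == "C")
  sum(l * params$weight_fun(e$r, params$d0))
}

#' Score predicted sites against a receptor
#'
#' Adds the three per-site descriptors -- hydrogen-bond term, refit water
#' energy, hydrophilicity and lipophilicity -- as columns.  Input order is
#' preserved.
#'
#' @param sites Site tibble (`x`, `y`, `z`), e.g. from [predict_sites()].
#' @param atoms Receptor atom tibble with roles assigned.
#' @param table Propensity table.
#' @param params A [score_params()] object.
#' @param model An [energy_model()].
#' @return `sites` with `hbond`, `energy`, `hydrophilicity`,
#'   `lipophilicity` columns.
#' @export
score_sites <- function(sites, atoms, table = read_propensity_table(),
                        params = score_params(), model = energy_model()) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0) {
    return(mutate(sites, hbond = double(), energy = double(),
                  hydrophilicity = double(), lipophilicity = double()))
  }
  pts <- xyz_matrix(sites)
  hb <- apply(pts, 1, hbond_term, atoms = atoms, params = params)
  sites$hbond <- hb
  sites$energy <- water_energy(hb, model)
  sites$hydrophilicity <- apply(pts, 1, hydrophilicity, atoms = atoms,
                                table = table, params = params)
  sites$lipophilicity <- apply(pts, 1, lipophilicity, atoms = atoms,
                               table = table, params = params)
  sites
}
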