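# All-subsets linear-model mining for the water energy model.
#
# Every non-empty subset of a library of scoring-function terms is fit by
# ordinary least squares against calculated water binding free energies,
# ranked by AIC, and the top candidates are compared by
# leave-one-group-out cross-validation (each group holds all measurements
# of one conserved water / protein system).  With 8 candidate terms the
# enumeration yields 255 models.

#' Default scoring-function term library
#'
#' Eight non-torsional energetic terms drawn from the two docking scoring
#' functions the mining procedure combines: the five empirical terms
#' (two gaussians, repulsion, hydrophobic, hydrogen bond) and the
#' force-field vdW, electrostatic and desolvation terms.  The force-field
#' hydrogen-bond term is dropped as redundant with the retained empirical
#' one, keeping the library at eight terms (and the all-subsets count at
#' 255).  Torsional terms do not apply to a rigid water molecule.
#'
#' @return Character vector of term names.
#' @export
default_term_library <- function() {
  c("vina_gauss1", "vina_gauss2", "vina_repulsion", "vina_hydrophobic",
    "vina_hbond", "ad4_vdw", "ad4_elec", "ad4_desolv")
}

#' Enumerate all non-empty term subsets
#'
#' @param terms Character vector of term names.
#' @return List of character vectors, ordered by subset size then name;
#'   `2^n - 1` subsets for `n` terms.
#' @export
enumerate_subsets <- function(terms) {
  stopifnot(length(terms) >= 1)
  out <- list()
  for (k in seq_along(terms)) {
    cmb <- combn(terms, k, simplify = FALSE)
    ord <- order(vapply(cmb, paste, "", collapse = " "))
    out <- c(out, cmb[ord])
  }
  out
}

check_term_matrix <- function(data, subset, response, group = NULL) {
  miss <- setdiff(c(subset, response, group), names(data))
  if (length(miss) > 0) {
    abort(paste0("term matrix lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyNA(data[c(subset, response, group)])) {
    abort("term matrix contains missing values")
  }
}

ols_solve <- function(X, y, term_names) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(setdiff(bad, "(Intercept)"), collapse = ", ")))
  }
  beta <- qr.coef(q, y)
  fitted <- drop(X %*% beta)
  list(coefficients = beta, fitted = fitted, rss = sum((y - fitted)^2))
}

#' Fit one term subset by OLS and compute its AIC
#'
#' Ordinary least squares with an intercept.  The default AIC dialect is
#' the Gaussian profile form `n * ln(RSS / n) + 2 * (k + 1)` with
#' `k = |subset| + 1` regression parameters (the `+ 1` counts the profiled
#' error variance).  The `"full"` dialect adds the constant
#' `n * ln(2 * pi) + n`, matching [stats::AIC()] on an `lm` fit.
#'
#' @param data Term-matrix tibble: one row per water, term columns, the
#'   response column, and (for cross-validation) a group column.
#' @param subset Character vector of term names to include.
#' @param response Name of the response column, kcal/mol.
#' @param aic_form `"profile"` (default) or `"full"`.
#' @return A list of class `ols_fit`: `terms`, `coefficients`, `rss`,
#'   `aic`, `k`, `n`.
#' @export
fit_ols_aic <- function(data, subset, response = "dg",
                        aic_form = c("profile", "full")) {
  aic_form <- arg_match(aic_form)
  check_term_matrix(data, subset, response)
  n <- nrow(data)
  k <- length(subset) + 1L
  if (n <= k) abort("need more rows than regression parameters")
  X <- cbind(`(Intercept)` = 1, as.matrix(data[subset]))
  y <- data[[response]]
  fit <- ols_solve(X, y, subset)
  # an exact interpolation has no meaningful Gaussian AIC: flag it as -Inf
  # rather than taking the log of accumulated rounding error
  rss_tol <- 1e-10 * max(1, sum(y^2))
  if (fit$rss < rss_tol) {
    aic <- -Inf
  } else {
    aic <- n * log(fit$rss / n) + 2 * (k + 1)
    if (aic_form == "full") aic <- aic + n * log(2 * pi) + n
  }
  structure(
    list(terms = subset, coefficients = fit$coefficients, rss = fit$rss,
         aic = aic, k = k, n = n, aic_form = aic_form),
    class = "ols_fit"
  )
}

#' Leave-group-out cross-validation error of a term subset
#'
#' Each fold holds out every row of one group, refits the subset on the
#' complement, and records the mean absolute prediction error on the
#' held-out rows; the returned value is the unweighted mean over folds.
#'
#' @inheritParams fit_ols_aic
#' @param group Name of the group-id column.
#' @return Mean absolute cross-validation error, kcal/mol.
#' @export
leave_group_out_cv <- function(data, subset, response = "dg",
                               group = "group") {
  check_term_matrix(data, subset, response, group)
  gids <- unique(data[[group]])
  if (length(gids) < 2) abort("leave-group-out CV needs at least 2 groups")
  k <- length(subset) + 1L
  errs <- vapply(gids, function(g) {
    test <- data[[group]] == g
    train <- data[!test, , drop = FALSE]
    if (nrow(train) <= k) {
      abort(sprintf("fold holding out group '%s' leaves only %d row(s) for %d parameters",
                    g, nrow(train), k))
    }
    X <- cbind(`(Intercept)` = 1, as.matrix(train[subset]))
    fit <- ols_solve(X, train[[response]], subset)
    Xt <- cbind(`(Intercept)` = 1, as.matrix(data[test, subset, drop = FALSE]))
    pred <- drop(Xt %*% fit$coefficients)
    mean(abs(pred - data[[response]][test]))
  }, numeric(1))
  mean(errs)
}

#' Mine the term library for the best water energy model
#'
#' Fits every non-empty subset of the term columns, ranks by AIC, runs
#' leave-group-out cross-validation on the `top_k` lowest-AIC candidates,
#' and returns the candidate with the smallest mean absolute CV error,
#' refit on all rows.  Ties break towards the smaller subset, then term
#' names.
#'
#' @inheritParams leave_group_out_cv
#' @param top_k Number of lowest-AIC candidates carried into CV.
#' @param terms Term columns to mine; default is every column other than
#'   the response and group.
#' @param aic_form AIC dialect, see [fit_ols_aic()].
#' @return An object of class `water_energy_fit` with [tidy()] and
#'   [glance()] methods.  Fields include the selected `terms`, the final
#'   `lm` fit, `cv_mae`, `baseline_mae` (leave-group-out error of the
#'   intercept-only mean predictor) and the full `candidates` ranking.
#' @export
select_model <- function(data, top_k = 30, response = "dg", group = "group",
                         terms = NULL, aic_form = c("profile", "full")) {
  aic_form <- arg_match(aic_form)
  terms <- terms %||% setdiff(names(data), c(response, group))
  stopifnot(length(terms) >= 1)
  subsets <- enumerate_subsets(terms)

  fits <- map(subsets, fit_ols_aic, data = data, response = response,
              aic_form = aic_form)
  cand <- tibble(
    terms = map_chr(subsets, paste, collapse = "+"),
    subset = subsets,
    k = map_int(fits, "k"),
    rss = map_dbl(fits, "rss"),
    aic = map_dbl(fits, "aic")
  ) |> arrange(.data$aic, .data$k, .data$terms)

  n_cv <- min(top_k, nrow(cand))
  cand$cv_mae <- NA_real_
  cand$cv_mae[seq_len(n_cv)] <- map_dbl(
    cand$subset[seq_len(n_cv)], leave_group_out_cv,
    data = data, response = response, group = group
  )

  top <- cand[seq_len(n_cv), ]
  best <- top[order(round(top$cv_mae, 12), top$k, top$terms), ][1, ]
  sel <- best$subset[[1]]

  fml <- stats::reformulate(sel, response = response)
  final <- lm(fml, data = data)
  baseline <- leave_group_out_cv(data, character(0), response = response,
                                 group = group)

  structure(
    list(terms = sel, fit = final,
         coefficients = coef(final),
         aic = best$aic, cv_mae = best$cv_mae, baseline_mae = baseline,
         n = nrow(data), k = best$k,
         r_squared = summary(final)$r.squared,
         sigma = summary(final)$sigma,
         candidates = select(cand, -"subset"),
         response = response, group = group, aic_form = aic_form),
    class = "water_energy_fit"
  )
}

#' @export
print.water_energy_fit <- function(x, ...) {
  cat("water energy model selected by all-subsets AIC + grouped CV\n")
  cat("  terms: ", paste(x$terms, collapse = " + "), "\n", sep = "")
  cat(sprintf("  AIC %.2f | CV MAE %.2f kcal/mol (mean-predictor baseline %.2f)\n",
              x$aic, x$cv_mae, x$baseline_mae))
  cat(sprintf("  R^2 %.2f | residual SE %.2f kcal/mol | n = %d\n",
              x$r_squared, x$sigma, x$n))
  invisible(x)
}

#' @rdname select_model
#' @param x A `water_energy_fit`.
#' @param ... Unused.
#' @method tidy water_energy_fit
#' @export
tidy.water_energy_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname select_model
#' @method glance water_energy_fit
#' @export
glance.water_energy_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, sigma = x$sigma, aic = x$aic,
    cv_mae = x$cv_mae, baseline_mae = x$baseline_mae,
    n = x$n, k = x$k
  )
}

#' Convert a selected single-term hydrogen-bond fit to an energy model
#'
#' When model mining selects the single hydrogen-bond term, its intercept
#' and slope define an [energy_model()] directly usable by
#' [score_sites()].
#'
#' @param fit A `water_energy_fit` whose selected subset is one term.
#' @return An [energy_model()].
#' @export
as_energy_model <- function(fit) {
  stopifnot(inherits(fit, "water_energy_fit"))
  if (length(fit$terms) != 1) {
    abort("as_energy_model needs a single-term fit")
  }
  energy_model(intercept = unname(fit$coefficients[["(Intercept)"]]),
               hbond_weight = unname(fit$coefficients[[fit$terms]]))
}
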