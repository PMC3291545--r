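# Retrospective labeling of predicted sites and bagged classification
# trees over the three per-site descriptors.
#
# A predicted apo site is "conserved" if a crystal water of the bound
# complex lies within 1.5 A, "displaced" if instead a ligand atom does
# (polar vs non-polar decided by the nearest such atom's hydrogen-bonding
# role), and "ambiguous" otherwise; ambiguous sites are excluded from
# training and from accuracy denominators.  The classifier is bootstrap
# aggregation of CART-style trees: each tree is fit to a resample of the
# data and class probabilities are the average of the leaf class
# proportions across trees.

#' Label predicted sites against the bound complex
#'
#' @param sites Site tibble (`x`, `y`, `z`).
#' @param crystal_waters Positions of the complex's crystallographic
#'   waters: tibble with `x`, `y`, `z` or a 3-column matrix.  May be
#'   empty.
#' @param ligand Ligand atom tibble with roles assigned (may be `NULL`).
#' @param cutoff Match radius, A.
#' @return A tibble with one row per site: `site`, `class`
#'   (`conserved` / `displaced` / `ambiguous`), `displaced_by`
#'   (`polar` / `nonpolar`, `NA` unless displaced) and `match_distance`.
#' @export
label_sites <- function(sites, crystal_waters, ligand = NULL, cutoff = 1.5) {
  stopifnot(is.data.frame(sites))
  n <- nrow(sites)
  if (n == 0) {
    return(tibble(site = integer(), class = character(),
                  displaced_by = character(), match_distance = double()))
  }
  pts <- xyz_matrix(sites)

  dw <- rep(Inf, n)
  cw <- if (!is.null(crystal_waters)) xyz_matrix(crystal_waters) else
    matrix(numeric(), ncol = 3)
  if (nrow(cw) > 0) dw <- apply(cross_dist(pts, cw), 1, min)

  dl <- rep(Inf, n)
  nearest_polar <- rep(NA, n)
  if (!is.null(ligand) && nrow(ligand) > 0) {
    stopifnot(all(c("is_donor", "is_acceptor") %in% names(ligand)))
    dmat <- cross_dist(pts, ligand)
    dl <- apply(dmat, 1, min)
    idx <- apply(dmat, 1, which.min)
    nearest_polar <- ligand$is_donor[idx] | ligand$is_acceptor[idx]
  }

  cls <- ifelse(dw <= cutoff, "conserved",
                ifelse(dl <= cutoff, "displaced", "ambiguous"))
  by <- ifelse(cls == "displaced",
               ifelse(nearest_polar, "polar", "nonpolar"), NA_character_)
  md <- ifelse(cls == "conserved", dw,
               ifelse(cls == "displaced", dl, pmin(dw, dl)))
  tibble(site = if ("site" %in% names(sites)) sites$site else seq_len(n),
         class = cls, displaced_by = by, match_distance = md)
}

# ---- bagged trees -------------------------------------------------------

rpart_ctrl <- function(minbucket, cp, maxdepth) {
  rpart::rpart.control(
    minsplit = 3 * minbucket, minbucket = minbucket, cp = cp,
    maxdepth = maxdepth, xval = 0,
    maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
  )
}

# flatten one rpart classification tree to a node table: binary node ids
# (children of k are 2k / 2k + 1), primary splits only (the fit is run
# with competing and surrogate splits disabled)
extract_tree <- function(fit, classes) {
  fr <- fit$frame
  ids <- as.integer(row.names(fr))
  leaf <- fr$var == "<leaf>"
  counts <- fr$yval2[, 1 + seq_along(classes), drop = FALSE]
  var <- ifelse(leaf, NA_character_, as.character(fr$var))
  threshold <- rep(NA_real_, nrow(fr))
  lt_left <- rep(NA, nrow(fr))
  if (any(!leaf)) {
    sp <- fit$splits
    # with maxcompete = maxsurrogate = 0, splits rows follow the non-leaf
    # frame rows in order
    stopifnot(nrow(sp) == sum(!leaf))
    threshold[!leaf] <- sp[, "index"]
    lt_left[!leaf] <- sp[, "ncat"] < 0
  }
  list(id = ids, var = var, threshold = threshold, lt_left = lt_left,
       counts = unname(counts))
}

predict_node_tree <- function(tree, X) {
  n <- nrow(X)
  id_index <- match(seq_len(max(tree$id)), tree$id)
  probs <- matrix(0, n, ncol(tree$counts))
  for (i in seq_len(n)) {
    node <- 1L
    repeat {
      row <- id_index[node]
      if (is.na(tree$var[row])) break
      v <- X[i, tree$var[row]]
      left <- if (tree$lt_left[row]) v < tree$threshold[row] else
        v >= tree$threshold[row]
      node <- if (left) 2L * node else 2L * node + 1L
    }
    cnt <- tree$counts[id_index[node], ]
    probs[i, ] <- cnt / sum(cnt)
  }
  probs
}

#' Train a bagged classification-tree model
#'
#' Fits `n_trees` CART-style trees (Gini splits, minimum leaf size 5, no
#' pruning by default) to bootstrap resamples of the data and aggregates
#' their leaf class proportions.  Deterministic given `seed`; the
#' bootstrap indices are recorded per tree.
#'
#' @param data Tibble holding the label and feature columns.
#' @param label Name of the class column (coerced to factor; at least two
#'   classes must be present).
#' @param features Feature column names; default the three per-site
#'   descriptors.
#' @param n_trees Number of bootstrap trees.
#' @param seed Integer seed controlling the bootstrap.
#' @param bootstrap Set `FALSE` to fit every tree to the full data
#'   (identity sample); with `n_trees = 1` this reduces the ensemble to a
#'   single classification tree.
#' @param minbucket,cp,maxdepth Tree-growing controls (rpart semantics).
#' @return An object of class `bagged_trees`.
#' @export
train_bagged_trees <- function(data, label = "label",
                               features = c("energy", "hydrophilicity",
                                            "lipophilicity"),
                               n_trees = 100, seed = 1, bootstrap = TRUE,
                               minbucket = 5, cp = 0, maxdepth = 30) {
  stopifnot(is.data.frame(data), label %in% names(data),
            all(features %in% names(data)), n_trees >= 1)
  y <- factor(data[[label]])
  if (nlevels(droplevels(y)) < 2) {
    abort("training data holds a single class; need at least two")
  }
  y <- droplevels(y)
  df <- data.frame(data[features], .class = y, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", features), response = ".class")
  ctrl <- rpart_ctrl(minbucket, cp, maxdepth)
  n <- nrow(df)

  idx <- withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    })
  })
  trees <- map(idx, function(ix) {
    fit <- rpart::rpart(fml, data = df[ix, , drop = FALSE],
                        method = "class",
                        parms = list(split = "gini"), control = ctrl)
    fit
  })
  nodes <- map(trees, extract_tree, classes = levels(y))
  structure(
    list(trees = trees, nodes = nodes, boot_idx = idx,
         classes = levels(y), features = features, n_trees = n_trees,
         seed = seed,
         params = list(minbucket = minbucket, cp = cp, maxdepth = maxdepth,
                       bootstrap = bootstrap)),
    class = "bagged_trees"
  )
}

#' Predict class probabilities from a bagged-tree model
#'
#' Each tree routes an observation to a leaf and contributes that leaf's
#' training-class proportions; the ensemble probability is the unweighted
#' mean over trees, so probabilities always sum to 1.
#'
#' @param object A `bagged_trees` model (trained or loaded from JSON).
#' @param newdata Tibble with the model's feature columns.
#' @param type `"prob"` for a tibble of per-class probabilities,
#'   `"class"` for the argmax class (ties to the first class in training
#'   order).
#' @param ... Unused.
#' @export
predict.bagged_trees <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- arg_match(type)
  X <- as.matrix(as.data.frame(newdata)[object$features])
  storage.mode(X) <- "double"
  acc <- matrix(0, nrow(X), length(object$classes))
  for (tr in object$nodes) acc <- acc + predict_node_tree(tr, X)
  probs <- acc / length(object$nodes)
  colnames(probs) <- object$classes
  if (type == "class") {
    return(factor(object$classes[max.col(probs, ties.method = "first")],
                  levels = object$classes))
  }
  as_tibble(probs)
}

#' @export
print.bagged_trees <- function(x, ...) {
  cat(sprintf("bagged classification trees: %d trees, classes %s, seed %d\n",
              x$n_trees, paste(x$classes, collapse = "/"), x$seed))
  invisible(x)
}

#' Serialize a bagged-tree model to versioned JSON
#'
#' Stores the node tables (split feature, threshold, direction, leaf class
#' counts), classes, features, seed and bootstrap indices, so a model can
#' be reloaded and applied without refitting.
#'
#' @param model A `bagged_trees` model.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_bagged_trees <- function(model, path) {
  stopifnot(inherits(model, "bagged_trees"))
  payload <- list(
    format = "waterplace-bagged-trees", version = 1L,
    classes = model$classes, features = model$features,
    n_trees = model$n_trees, seed = model$seed, params = model$params,
    boot_idx = model$boot_idx,
    trees = map(model$nodes, function(tr) {
      list(id = tr$id, var = tr$var, threshold = tr$threshold,
           lt_left = tr$lt_left, counts = tr$counts)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a bagged-tree model from JSON
#'
#' @param path JSON file written by [write_bagged_trees()].
#' @return A `bagged_trees` model (node tables only; predictions are
#'   identical to the in-memory model's).
#' @export
read_bagged_trees <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "waterplace-bagged-trees")) {
    abort("not a waterplace bagged-trees JSON file")
  }
  nodes <- map(seq_len(p$n_trees), function(i) {
    tr <- if (is.data.frame(p$trees)) lapply(p$trees, `[[`, i) else p$trees[[i]]
    cnt <- tr$counts
    if (is.list(cnt)) cnt <- do.call(rbind, cnt)
    if (!is.matrix(cnt)) cnt <- matrix(cnt, ncol = length(p$classes))
    list(id = as.integer(tr$id), var = as.character(tr$var),
         threshold = as.numeric(tr$threshold),
         lt_left = as.logical(tr$lt_left), counts = cnt)
  })
  structure(
    list(trees = NULL, nodes = nodes, boot_idx = p$boot_idx,
         classes = p$classes, features = p$features,
         n_trees = p$n_trees, seed = p$seed, params = p$params),
    class = "bagged_trees"
  )
}

#' Leave-protein-out cross-validation of the classifier
#'
#' One fold per protein: all of a protein's waters form the test set, a
#' bagged-tree model is trained on the remaining proteins, and the
#' held-out waters are classified by their highest-probability class.
#' Reports fold-equal mean accuracy, pooled accuracy, and the per-class
#' breakdown; folds without labeled waters are skipped with a warning.
#'
#' @param data Tibble with a protein-id column, the label column and the
#'   feature columns.  Rows with `NA` labels (ambiguous sites) are
#'   dropped.
#' @param protein Name of the protein-id column.
#' @inheritParams train_bagged_trees
#' @return An object of class `loco_cv` with [tidy()] and [glance()]
#'   methods: per-fold accuracies, per-prediction records, fold-equal
#'   `mean_accuracy`, `pooled_accuracy` and `per_class` accuracies.
#' @export
leave_protein_out_cv <- function(data, protein = "protein", label = "label",
                                 features = c("energy", "hydrophilicity",
                                              "lipophilicity"),
                                 n_trees = 100, seed = 1, ...) {
  stopifnot(protein %in% names(data))
  prots <- unique(data[[protein]])
  data <- data[!is.na(data[[label]]), , drop = FALSE]
  if (length(prots) < 2) abort("need at least 2 proteins for grouped CV")

  folds <- list(); preds <- list()
  for (i in seq_along(prots)) {
    p <- prots[[i]]
    test <- data[[protein]] == p
    if (!any(test)) {
      warn(sprintf("protein '%s' has no labeled waters; fold skipped", p))
      next
    }
    model <- train_bagged_trees(data[!test, , drop = FALSE], label = label,
                                features = features, n_trees = n_trees,
                                seed = seed + i, ...)
    probs <- predict(model, data[test, , drop = FALSE], type = "prob")
    pm <- as.matrix(probs)
    pred <- model$classes[max.col(pm, ties.method = "first")]
    truth <- as.character(data[[label]][test])
    preds[[length(preds) + 1]] <- tibble(
      protein = p, truth = truth, pred = pred,
      max_prob = pm[cbind(seq_len(nrow(pm)), max.col(pm, ties.method = "first"))],
      correct = pred == truth
    )
    folds[[length(folds) + 1]] <- tibble(
      protein = p, n = sum(test), accuracy = mean(pred == truth)
    )
  }
  folds <- dplyr::bind_rows(folds)
  preds <- dplyr::bind_rows(preds)
  per_class <- preds |>
    group_by(class = .data$truth) |>
    summarise(n = dplyr::n(), accuracy = mean(.data$correct),
              .groups = "drop")
  structure(
    list(folds = folds, predictions = preds,
         mean_accuracy = mean(folds$accuracy),
         pooled_accuracy = mean(preds$correct),
         per_class = per_class),
    class = "loco_cv"
  )
}

#' @export
print.loco_cv <- function(x, ...) {
  cat(sprintf(
    "leave-protein-out CV: %d folds | mean accuracy %.1f%% (pooled %.1f%%)\n",
    nrow(x$folds), 100 * x$mean_accuracy, 100 * x$pooled_accuracy))
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("  %-12s %.1f%% (n = %d)\n", x$per_class$class[i],
                100 * x$per_class$accuracy[i], x$per_class$n[i]))
  }
  invisible(x)
}

#' @rdname leave_protein_out_cv
#' @param x A `loco_cv` object.
#' @param ... Unused.
#' @method tidy loco_cv
#' @export
tidy.loco_cv <- function(x, ...) x$folds

#' @rdname leave_protein_out_cv
#' @method glance loco_cv
#' @export
glance.loco_cv <- function(x, ...) {
  tibble(n_folds = nrow(x$folds), n_waters = nrow(x$predictions),
         mean_accuracy = x$mean_accuracy,
         pooled_accuracy = x$pooled_accuracy)
}

#' Classification accuracy by confidence bin
#'
#' Bins predictions by their maximum class probability into
#' `[0.5, 0.6) ... [0.9, 1.0]` and reports per-bin counts and accuracy
#' (`NA` for empty bins).  A well-calibrated classifier shows
#' non-decreasing accuracy across bins.
#'
#' @param predictions Tibble with columns `max_prob` and `correct`
#'   (e.g. the `predictions` element of a [leave_protein_out_cv()]
#'   result).
#' @param breaks Bin edges over the max-probability range.
#' @return Tibble: `bin`, `lower`, `upper`, `n`, `accuracy`.
#' @export
confidence_bins <- function(predictions,
                            breaks = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)) {
  stopifnot(nrow(predictions) > 0,
            all(c("max_prob", "correct") %in% names(predictions)))
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1]
  res <- map2(lower, upper, function(lo, hi) {
    inb <- predictions$max_prob >= lo &
      (predictions$max_prob < hi | (hi == max(breaks) & predictions$max_prob <= hi))
    tibble(bin = sprintf("[%.1f,%.1f%s", lo, hi,
                         if (hi == max(breaks)) "]" else ")"),
           lower = lo, upper = hi, n = sum(inb),
           accuracy = if (any(inb)) mean(predictions$correct[inb]) else NA_real_)
  })
  dplyr::bind_rows(res)
}

#' Apply the two-model cascade to scored sites
#'
#' Model one assigns the probability that a site is conserved vs
#' displaced; model two, trained on displaced sites only, splits
#' displacement into polar vs non-polar.  Returns marginal probabilities
#' for all four outcomes plus the argmax call.
#'
#' @param sites Scored site tibble (columns the models' features).
#' @param model_role `bagged_trees` model over conserved/displaced.
#' @param model_displacement `bagged_trees` model over polar/nonpolar.
#' @return `sites` with columns `p_conserved`, `p_displaced`,
#'   `p_polar`, `p_nonpolar` (the latter two conditional on displacement,
#'   scaled by `p_displaced`) and `predicted_class`.
#' @export
classify_sites <- function(sites, model_role, model_displacement = NULL) {
  pr <- predict(model_role, sites, type = "prob")
  stopifnot(all(c("conserved", "displaced") %in% names(pr)))
  out <- mutate(sites, p_conserved = pr$conserved, p_displaced = pr$displaced)
  if (!is.null(model_displacement)) {
    pd <- predict(model_displacement, sites, type = "prob")
    out$p_polar <- out$p_displaced * pd$polar
    out$p_nonpolar <- out$p_displaced * pd$nonpolar
    out$predicted_class <- ifelse(
      out$p_conserved >= out$p_displaced, "conserved",
      ifelse(pd$polar >= pd$nonpolar, "displaced_polar", "displaced_nonpolar")
    )
  } else {
    out$predicted_class <- ifelse(out$p_conserved >= out$p_displaced,
                                  "conserved", "displaced")
  }
  out
}
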