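# Factorial sweep execution and the downstream analysis pipeline:
# rank-based multifactor comparisons, 1-D K-means clustering of the
# colocalisation score, and gradient-boosted attribution with SHAP values.

#' Define a factorial sweep grid over the six variability factors
#'
#' @param motility,intensity,fluid,pocket_volume,occlusion_ratio,release
#'   factor levels to cross (defaults: the full motility-study grid).
#' @return tibble of case definitions, one row per case.
#' @export
sweep_grid <- function(motility = c("segmentation", "peristalsis"),
                       intensity = c("light", "moderate", "vigorous"),
                       fluid = c("water_37C", "nutridrink_default"),
                       pocket_volume = c(2, 10),
                       occlusion_ratio = c(0.3, 0.5, 0.7),
                       release = c("most_occluded", "least_occluded")) {
  g <- expand.grid(motility = motility, intensity = intensity, fluid = fluid,
                   pocket_volume = pocket_volume,
                   occlusion_ratio = occlusion_ratio, release = release,
                   stringsAsFactors = FALSE)
  out <- tibble::as_tibble(g)
  out$case_id <- seq_len(nrow(out))
  out
}

#' Execute a sweep of motility cases
#'
#' Runs every case of the grid deterministically (the solvers are
#' deterministic given the configuration; `seed` only feeds downstream
#' analyses), collects the per-case delivery summaries, and attaches the
#' ensemble-normalised colocalisation scores. Individual case failures are
#' caught, recorded and excluded.
#'
#' @param grid a [sweep_grid()] tibble.
#' @param resolution preset name or list for all cases.
#' @param n_periods periods per case (default 30; reduce for quick scans).
#' @param seed stored in the result for downstream clustering/attribution.
#' @param progress print one line per case?
#' @return a `sweep_result` list: `table` (tibble of class `sweep_table`),
#'   `results` (case_result list), `failures`.
#' @export
run_sweep <- function(grid, resolution = "coarse", n_periods = 30L,
                      seed = 1L, progress = interactive()) {
  results <- vector("list", nrow(grid))
  failures <- list()
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    res <- tryCatch({
      case <- motility_case(row$motility, row$intensity, row$fluid,
                            row$pocket_volume, row$occlusion_ratio,
                            row$release, n_periods = n_periods)
      run_case(case, resolution)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(case_id = row$case_id,
                                                message = conditionMessage(res))
      if (progress) message("case ", row$case_id, " FAILED: ",
                            conditionMessage(res))
    } else {
      res$case_id <- row$case_id
      results[[i]] <- res
      if (progress) message("case ", row$case_id, " done")
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  results <- results[ok]
  tab <- grid[ok, , drop = FALSE]
  gl <- dplyr::bind_rows(lapply(results, glance.case_result))
  tab <- dplyr::bind_cols(tab, gl)
  if (length(results) >= 2) {
    cs <- colocalise(results)
    tab$cs <- cs$cs[match(tab$case_id, cs$case_id)]
  }
  class(tab) <- c("sweep_table", class(tab))
  structure(list(table = tab, results = results, failures = failures,
                 seed = seed, resolution = resolution),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cases (%d failed), resolution %s\n",
              nrow(x$table), length(x$failures),
              if (is.character(x$resolution)) x$resolution else "custom"))
  invisible(x)
}

#' Grouped summaries with rank-based significance tests
#'
#' Summarises a response by the levels of one variability factor and tests
#' for location differences with the appropriate non-parametric test: the
#' Mann-Whitney (Wilcoxon rank-sum) test for two groups, or Kruskal-Wallis
#' followed by pairwise Dunn tests (Holm-adjusted) for more.
#'
#' @param table a sweep table (tibble with the factor and response columns).
#' @param factor name of the grouping column.
#' @param response name of the numeric response column.
#' @return list with `summary` (per-group median and quartiles), `test`
#'   (the global rank test, htest-like list), and `pairwise` (Dunn tibble,
#'   `NULL` for two groups).
#' @export
multifactor_compare <- function(table, factor, response) {
  x <- table[[response]]
  gvec <- as.factor(table[[factor]])
  if (any(tapply(x, gvec, length) < 2) || nlevels(gvec) < 2) {
    stop("multifactor_compare needs >= 2 groups with >= 2 observations each")
  }
  summ <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(g = gvec, x = x), .data$g),
    n = dplyr::n(),
    q1 = stats::quantile(.data$x, 0.25),
    median = stats::median(.data$x),
    q3 = stats::quantile(.data$x, 0.75),
    .groups = "drop"
  )
  names(summ)[1] <- factor
  if (nlevels(gvec) == 2) {
    lv <- levels(gvec)
    # exact rank enumeration when there are no ties; normal approximation
    # (without the continuity fudge) otherwise
    te <- suppressWarnings(
      stats::wilcox.test(x[gvec == lv[1]], x[gvec == lv[2]],
                         exact = !any(duplicated(x)), correct = FALSE)
    )
    list(summary = summ, test = list(method = "Mann-Whitney U",
                                     statistic = unname(te$statistic),
                                     p.value = te$p.value),
         pairwise = NULL)
  } else {
    kw <- stats::kruskal.test(x, gvec)
    list(summary = summ,
         test = list(method = "Kruskal-Wallis",
                     statistic = unname(kw$statistic), p.value = kw$p.value),
         pairwise = dunn_test(x, gvec))
  }
}

#' Dunn's pairwise post-hoc test on ranks
#'
#' Pairwise z statistics on mean ranks with tie correction, following a
#' Kruskal-Wallis test; p-values are two-sided normal and Holm-adjusted.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()].
#' @return tibble with group pair, z, p and adjusted p.
#' @export
dunn_test <- function(x, g, adjust = "holm") {
  g <- as.factor(g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    tibble::tibble(group1 = i, group2 = j, z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' K-means clustering of colocalisation scores
#'
#' One-dimensional K-means on the CS column, deterministic given the seed
#' (many restarts), with clusters relabelled in increasing order of mean CS.
#'
#' @param table a sweep table with a `cs` column.
#' @param k number of clusters (default 4).
#' @param seed RNG seed for the K-means restarts.
#' @param nstart restarts.
#' @return a `cluster_result`: `table` with a `cluster` column, `centers`,
#'   `sizes`, and per-cluster mean CS.
#' @export
cluster_cases <- function(table, k = 4L, seed = 1L, nstart = 50L) {
  cs <- table$cs
  if (is.null(cs)) stop("table has no `cs` column")
  if (k < 2) stop("k must be >= 2")
  if (k > length(unique(cs))) {
    stop("k = ", k, " exceeds the number of distinct CS values (",
         length(unique(cs)), ")")
  }
  set.seed(seed)
  km <- if (k == length(cs)) {
    # every case its own cluster
    list(cluster = rank(cs, ties.method = "first"),
         centers = matrix(sort(cs)), tot.withinss = 0)
  } else {
    stats::kmeans(cs, centers = k, nstart = nstart, iter.max = 100L)
  }
  ord <- order(km$centers)
  relabel <- match(seq_len(k), ord)
  cl <- relabel[km$cluster]
  tab <- table
  tab$cluster <- cl
  means <- vapply(seq_len(k), function(q) mean(cs[cl == q]), numeric(1))
  structure(list(table = tab,
                 centers = sort(as.vector(km$centers)),
                 sizes = as.vector(table(cl)),
                 cluster_mean_cs = means,
                 k = k, seed = seed,
                 withinss = km$tot.withinss),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d (seed %d)\n", x$k, x$seed))
  for (q in seq_len(x$k)) {
    cat(sprintf("  cluster %d: n = %d, mean CS = %.3f\n",
                q, x$sizes[q], x$cluster_mean_cs[q]))
  }
  invisible(x)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$k), n = x$sizes,
                 mean_cs = x$cluster_mean_cs, center = x$centers)
}

# ---- gradient-boosted attribution ---------------------------------------

# one-hot encode categoricals and Min-Max scale all columns to [0, 1]
encode_features <- function(table) {
  feats <- c("motility", "intensity", "fluid", "pocket_volume",
             "occlusion_ratio", "release")
  feats <- intersect(feats, names(table))
  df <- as.data.frame(table[, feats])
  for (f in feats) if (is.character(df[[f]])) df[[f]] <- factor(df[[f]])
  mm <- stats::model.matrix(~ . - 1, data = df,
                            contrasts.arg = lapply(
                              Filter(function(col) is.factor(df[[col]]), feats),
                              function(col) stats::contrasts(df[[col]],
                                                             contrasts = FALSE)
                            ) |> stats::setNames(Filter(function(col)
                              is.factor(df[[col]]), feats)))
  rng <- apply(mm, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  scaled <- sweep(sweep(mm, 2, rng[1, ], `-`), 2, span, `/`)
  scaled
}

#' Gradient-boosted attribution of colocalisation variability
#'
#' Trains a gradient-boosted tree regression of CS on the six variability
#' factors (one-hot encoded, Min-Max scaled to `[0, 1]`), with an 80/20
#' train/test split and a 3-fold cross-validated grid search over number of
#' trees (50-700), learning rate (0.005-0.2), maximum depth (3-9) and
#' subsample ratio (0.6-1.0). Per-case SHAP values are exact TreeSHAP
#' contributions; features are ranked by mean absolute SHAP.
#'
#' By default the model is trained on the largest cluster of a k-cluster
#' CS clustering (the bulk of cases); set `train_on = "all"` to use every
#' case.
#'
#' @param table a sweep table with `cs` (a `sweep_result` is accepted).
#' @param seed RNG seed controlling split, fold assignment and training.
#' @param train_on `"largest_cluster"` or `"all"`.
#' @param k clusters used when `train_on = "largest_cluster"`.
#' @param param_grid data frame of candidate hyperparameters (columns
#'   `nrounds`, `eta`, `max_depth`, `subsample`); a focused default within
#'   the stated ranges is used when `NULL`.
#' @return an `attribution_result`: SHAP matrix, ranking, held-out fit
#'   metrics, chosen hyperparameters and the fitted model.
#' @export
attribute_factors <- function(table, seed = 1L,
                              train_on = c("largest_cluster", "all"),
                              k = 4L, param_grid = NULL) {
  train_on <- match.arg(train_on)
  if (inherits(table, "sweep_result")) table <- table$table
  if (is.null(table$cs)) stop("table has no `cs` column")
  if (train_on == "largest_cluster") {
    clr <- cluster_cases(table, k = k, seed = seed)
    biggest <- which.max(clr$sizes)
    table <- clr$table[clr$table$cluster == biggest, , drop = FALSE]
  }
  if (nrow(table) < 20) {
    warning("attribution on ", nrow(table),
            " cases; >= 20 recommended for a stable split")
  }
  y <- table$cs
  if (stats::sd(y) < 1e-12) {
    stop("degenerate target: CS is constant across the selected cases")
  }
  X <- encode_features(table)

  set.seed(seed)
  n <- nrow(X)
  test_idx <- sample.int(n, size = max(1L, round(0.2 * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  Xte <- X[test_idx, , drop = FALSE]; yte <- y[test_idx]

  if (is.null(param_grid)) {
    param_grid <- expand.grid(nrounds = c(50L, 200L, 700L),
                              eta = c(0.01, 0.05, 0.2),
                              max_depth = c(3L, 6L, 9L),
                              subsample = c(0.6, 1.0))
  }
  folds <- sample(rep_len(1:3, length(ytr)))
  cv_rmse <- vapply(seq_len(nrow(param_grid)), function(pi_) {
    pr <- param_grid[pi_, ]
    errs <- vapply(1:3, function(fd) {
      tr <- folds != fd
      bst <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = pr$eta,
                      max_depth = pr$max_depth, subsample = pr$subsample,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(Xtr[tr, , drop = FALSE],
                                    label = ytr[tr]),
        nrounds = pr$nrounds, verbose = 0
      )
      pred <- stats::predict(bst, xgboost::xgb.DMatrix(Xtr[!tr, , drop = FALSE]))
      sqrt(mean((pred - ytr[!tr])^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- param_grid[which.min(cv_rmse), ]

  bst <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = best$eta,
                  max_depth = best$max_depth, subsample = best$subsample,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(Xtr, label = ytr),
    nrounds = best$nrounds, verbose = 0
  )
  pred_te <- stats::predict(bst, xgboost::xgb.DMatrix(Xte))
  mse <- mean((pred_te - yte)^2)
  r2 <- 1 - sum((pred_te - yte)^2) / sum((yte - mean(yte))^2)

  dall <- xgboost::xgb.DMatrix(X)
  contrib <- stats::predict(bst, dall, predcontrib = TRUE)
  colnames(contrib) <- c(colnames(X), "BIAS")
  shap <- contrib[, colnames(X), drop = FALSE]
  pred_all <- stats::predict(bst, dall)
  additivity <- max(abs(rowSums(contrib) - pred_all))

  # aggregate one-hot columns back to their parent factor
  parent <- vapply(colnames(X), function(cn) {
    hits <- c("motility", "intensity", "fluid", "pocket_volume",
              "occlusion_ratio", "release")
    m <- hits[startsWith(cn, hits)]
    if (length(m)) m[which.max(nchar(m))] else cn
  }, "")
  mean_abs <- tapply(colMeans(abs(shap)), parent, sum)
  ranking <- tibble::tibble(feature = names(mean_abs),
                            mean_abs_shap = as.vector(mean_abs))
  ranking <- ranking[order(-ranking$mean_abs_shap), ]

  structure(list(
    ranking = ranking, shap = shap, feature_parent = parent,
    metrics = tibble::tibble(mse = mse, rmse = sqrt(mse), r2 = r2,
                             n_train = length(ytr), n_test = length(yte)),
    best_params = tibble::as_tibble(best), cv_rmse = min(cv_rmse),
    additivity_error = additivity,
    model = bst, features = X, cs = y, seed = seed,
    train_on = train_on
  ), class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> trained on %s (%d cases), seed %d\n",
              x$train_on, nrow(x$features), x$seed))
  cat(sprintf("  held-out: MSE %.4f, RMSE %.4f, R2 %.3f\n",
              x$metrics$mse, x$metrics$rmse, x$metrics$r2))
  cat("  mean |SHAP| ranking:\n")
  for (i in seq_len(nrow(x$ranking))) {
    cat(sprintf("    %d. %s (%.4f)\n", i, x$ranking$feature[i],
                x$ranking$mean_abs_shap[i]))
  }
  invisible(x)
}

#' @method tidy attribution_result
#' @export
tidy.attribution_result <- function(x, ...) x$ranking

#' @method glance attribution_result
#' @export
glance.attribution_result <- function(x, ...) {
  dplyr::bind_cols(x$metrics, x$best_params,
                   tibble::tibble(additivity_error = x$additivity_error))
}
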