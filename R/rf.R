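#' Random-forest scan configuration
#'
#' Defaults follow the standard marker-selection protocol: 5,000 regression
#' trees, an mtry grid of 3, 6, 12, 24, 48, 96 tuned by out-of-bag variance
#' explained, a 1000-permutation per-marker null, and alpha 0.05.
#' \code{perm_trees} may be reduced below \code{n_trees} for desk-scale runs;
#' the observed forest then also uses \code{perm_trees} so observed and null
#' importances stay exchangeable.
#'
#' @param n_trees trees in the tuning/observed forests.
#' @param mtry_grid candidate mtry values.
#' @param n_perm permutations of the response for the null distribution.
#' @param alpha significance level of the per-marker test.
#' @param perm_trees trees per forest in the permutation phase (default
#'   \code{n_trees}).
#' @param min_node minimum node size before splitting stops (default 5).
#' @param seed integer seed.
#' @export
rf_config <- function(n_trees = 5000L, mtry_grid = c(3L, 6L, 12L, 24L, 48L, 96L),
                      n_perm = 1000L, alpha = 0.05, perm_trees = n_trees,
                      min_node = 5L, seed = 1L) {
  stopifnot(n_trees >= 1, length(mtry_grid) >= 1, all(mtry_grid >= 1),
            alpha > 0, alpha < 1, n_perm >= 1, perm_trees >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 mtry_grid = as.integer(sort(unique(mtry_grid))),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 perm_trees = as.integer(perm_trees),
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "rf_config")
}

.rf_scores <- function(markers) {
  if (inherits(markers, "marker_matrix")) markers$scores else {
    s <- as.matrix(markers); storage.mode(s) <- "integer"; s
  }
}

#' Fit one regression forest (binary predictors)
#'
#' Bagged fully-grown CART trees with \code{mtry} candidate markers per
#' split. Returns the out-of-bag MSE, variance explained
#' \code{1 - MSE/Var(y)} (population variance of the response), and, if
#' requested, unscaled permutation importance (mean increase in OOB MSE when
#' a marker's out-of-bag values are shuffled).
#'
#' @param markers \code{marker_matrix} or binary matrix.
#' @param y numeric response.
#' @param n_trees,mtry,min_node forest parameters.
#' @param importance compute IncMSE importance (default TRUE).
#' @return list: \code{oob_pred}, \code{mse_oob}, \code{var_explained},
#'   \code{importance} (named).
#' @export
rf_fit <- function(markers, y, n_trees = 500L, mtry = NULL, min_node = 5L,
                   importance = TRUE) {
  X <- .rf_scores(markers)
  y <- .as_y(y, nrow(X))
  m <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(m / 3))
  if (mtry > m) stop("mtry exceeds number of markers")
  if (stats::var(y) == 0) warning("constant response: all importances are 0")
  fit <- rf_forest(X, y, as.integer(n_trees), as.integer(mtry),
                   as.integer(min_node), isTRUE(importance))
  vy <- mean((y - mean(y))^2)
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(X)
  list(oob_pred = as.numeric(fit$oob_pred), mse_oob = fit$mse_oob,
       var_explained = if (vy > 0) 1 - fit$mse_oob / vy else 0,
       importance = imp)
}

#' Tune mtry by out-of-bag variance explained
#'
#' Fits one forest per grid value and returns the mtry maximizing
#' \code{1 - MSE_OOB / Var(y)}; ties go to the smaller mtry, grid values
#' larger than the marker count are skipped with a warning.
#'
#' @param markers \code{marker_matrix} or binary matrix.
#' @param y numeric response.
#' @param cfg an \code{\link{rf_config}}.
#' @return list: \code{best_mtry}, \code{grid} (data.frame mtry,
#'   var_explained).
#' @export
tune_mtry <- function(markers, y, cfg = rf_config()) {
  X <- .rf_scores(markers)
  grid <- cfg$mtry_grid
  bad <- grid > ncol(X)
  if (any(bad)) {
    warning("mtry value(s) ", paste(grid[bad], collapse = ", "),
            " exceed marker count; skipped")
    grid <- grid[!bad]
  }
  if (!length(grid)) stop("no valid mtry values in grid")
  set.seed(cfg$seed)
  ve <- vapply(grid, function(mt)
    rf_fit(X, y, cfg$n_trees, mt, cfg$min_node, importance = FALSE)$var_explained,
    0)
  best <- grid[which.max(ve)]  # which.max takes the first (smallest) on ties
  list(best_mtry = best, grid = data.frame(mtry = grid, var_explained = ve))
}

#' Per-marker importance at a fixed mtry
#'
#' @inheritParams tune_mtry
#' @param mtry candidate markers per split.
#' @return named numeric vector of IncMSE importances.
#' @export
rf_importance <- function(markers, y, mtry, cfg = rf_config()) {
  set.seed(cfg$seed)
  rf_fit(markers, y, cfg$n_trees, mtry, cfg$min_node, importance = TRUE)$importance
}

#' Random-forest marker scan with a per-marker permutation null
#'
#' Tunes mtry on the observed response, computes observed importances, then
#' refits the forest on \code{n_perm} permutations of the response — each
#' permutation destroying every marker-trait association while preserving the
#' marker correlation structure — and stores each marker's importances across
#' permutations as its own null distribution. A marker is significant iff its
#' observed importance exceeds the empirical (1 - alpha) quantile of its own
#' null; the permutation p-value is \code{(1 + #null >= obs) / (1 + n_perm)}.
#' mtry is tuned once and held fixed for all permutation runs; both the
#' observed and null forests use \code{perm_trees} trees so the comparison is
#' exchangeable.
#'
#' @inheritParams tune_mtry
#' @return class \code{rf_scan}: data.frame (marker, inc_mse, null_q,
#'   p_perm, significant) with attributes \code{mtry},
#'   \code{oob_var_explained}, \code{null} (markers x n_perm matrix).
#' @export
rf_permutation_scan <- function(markers, y, cfg = rf_config()) {
  X <- .rf_scores(markers)
  y <- .as_y(y, nrow(X))
  if (cfg$perm_trees < 100L)
    warning("perm_trees < 100: per-marker null distributions will be noisy")
  tm <- tune_mtry(markers, y, cfg)
  set.seed(cfg$seed + 1L)
  obs <- rf_fit(X, y, cfg$perm_trees, tm$best_mtry, cfg$min_node, TRUE)
  null <- matrix(NA_real_, ncol(X), cfg$n_perm,
                 dimnames = list(colnames(X), NULL))
  set.seed(cfg$seed + 2L)
  for (b in seq_len(cfg$n_perm)) {
    yb <- y[sample.int(length(y))]
    null[, b] <- rf_fit(X, yb, cfg$perm_trees, tm$best_mtry, cfg$min_node,
                        TRUE)$importance
  }
  # order-statistic (1 - alpha) quantile of each marker's own null
  k <- min(cfg$n_perm, max(1L, ceiling((1 - cfg$alpha) * cfg$n_perm)))
  nq <- apply(null, 1L, function(v) sort(v)[k])
  pp <- (1 + rowSums(null >= obs$importance)) / (1 + cfg$n_perm)
  out <- data.frame(marker = colnames(X), inc_mse = obs$importance,
                    null_q = nq, p_perm = pp,
                    significant = obs$importance > nq, row.names = NULL)
  class(out) <- c("rf_scan", "data.frame")
  attr(out, "mtry") <- tm$best_mtry
  attr(out, "oob_var_explained") <- obs$var_explained
  attr(out, "null") <- null
  out
}

#' Pairwise overlap of named marker sets
#'
#' Intersection counts and Jaccard overlap for every pair of selections
#' (e.g. RF vs each linear model), in long format.
#'
#' @param sets named list of character vectors over a common marker universe.
#' @return data.frame: set1, set2, n1, n2, overlap, jaccard.
#' @export
compare_selections <- function(sets) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  nm <- names(sets)
  rows <- list()
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i >= j) next
    a <- unique(sets[[i]]); b <- unique(sets[[j]])
    ov <- length(intersect(a, b)); un <- length(union(a, b))
    rows[[length(rows) + 1L]] <- data.frame(
      set1 = nm[i], set2 = nm[j], n1 = length(a), n2 = length(b),
      overlap = ov, jaccard = if (un > 0) ov / un else NA_real_)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write an RF scan as TSV
#' @param scan an \code{rf_scan}; \code{path} output file.
#' @param path file path.
#' @export
write_rf_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
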