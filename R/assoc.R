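## Single-marker association scans: the four classical models of increasing
## complexity (naive OLS; + structure covariates Q; + kinship random effect
## via spectral REML; Q+K), multiple-testing correction, and per-subpopulation
## trait summaries.

# coerce a response to a plain named numeric vector
.as_y <- function(y, n) {
  if (inherits(y, "phenotype_table")) {
    if (ncol(y$values) != 1L)
      stop("supply a single trait (one column) to a scan")
    y <- y$values[, 1L]
  }
  y <- as.numeric(y)
  if (length(y) != n) stop("response length does not match accession count")
  if (!all(is.finite(y))) stop("response must be finite")
  y
}

# Q design columns: K-1 memberships (rows sum to one, so the last is dropped)
.q_design <- function(Q) {
  if (is.null(Q)) return(NULL)
  m <- unclass_q(Q)
  if (ncol(m) <= 1L) return(NULL)
  m[, -ncol(m), drop = FALSE]
}

# Core vectorised OLS scan of each marker column against y given covariates.
# Returns per-marker effect, t statistic, df, p, incremental R^2 (vs tss).
.scan_core <- function(M, y, X0, tss = NULL) {
  n <- length(y)
  qr0 <- qr(X0)
  My <- qr.resid(qr0, y)
  MX <- qr.resid(qr0, M)
  sxx <- colSums(MX^2)
  cs <- colSums(scale(M, center = TRUE, scale = FALSE)^2)
  testable <- sxx > pmax(cs, .Machine$double.eps) * 1e-9 & cs > 0
  rss0 <- sum(My^2)
  if (is.null(tss)) tss <- rss0
  sxy <- as.numeric(crossprod(MX, My))
  df <- n - ncol(X0) - 1L
  beta <- ifelse(testable, sxy / sxx, NA_real_)
  rss1 <- pmax(rss0 - ifelse(testable, sxy^2 / sxx, 0), 0)
  se <- sqrt(rss1 / df / sxx)
  stat <- ifelse(testable & se > 0, beta / se, ifelse(testable, Inf, NA_real_))
  p <- ifelse(is.na(stat), NA_real_,
              pmax(2 * stats::pt(-abs(stat), df), .Machine$double.xmin))
  r2 <- ifelse(testable, pmax((rss0 - rss1) / tss, 0), NA_real_)
  list(effect = beta, stat = stat, df = df, p = p, r2 = pmin(r2, 1),
       rss0 = rss0, tss = tss)
}

.assoc_result <- function(markers, core, model_id, trait = "trait",
                          extra = list()) {
  out <- data.frame(marker = colnames(markers$scores), effect = core$effect,
                    stat = core$stat, df = core$df, p_raw = core$p,
                    p_adj = NA_real_, r2 = core$r2, model = model_id,
                    trait = trait, row.names = NULL)
  class(out) <- c("assoc_scan", "data.frame")
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Naive single-marker scan (model 1)
#'
#' Ordinary least squares \code{y = mu + beta * marker + e} per marker; the
#' two-sided t test of beta = 0 (equivalently the one-df F test, or a pooled
#' two-sample t test since the marker has two classes). No structure
#' correction — the baseline whose false-positive inflation the corrected
#' models are judged against.
#'
#' @param markers a \code{marker_matrix}.
#' @param y numeric response (or single-trait \code{phenotype_table}).
#' @param trait trait label carried into the result.
#' @return an \code{assoc_scan} data.frame: marker, effect, stat, df, p_raw,
#'   p_adj (NA until a correction is applied), r2, model, trait.
#' @export
scan_naive <- function(markers, y, trait = "trait") {
  y <- .as_y(y, nrow(markers$scores))
  X0 <- matrix(1, length(y), 1L)
  .assoc_result(markers, .scan_core(markers$scores, y, X0), 1L, trait)
}

#' Structure-corrected scan (model 2)
#'
#' Adds the admixture memberships Q as fixed covariates (K-1 columns, since
#' rows sum to one): \code{y = mu + Q gamma + beta * marker + e}, partial
#' t/F test of beta. Markers collinear with the Q columns are flagged
#' untestable (p = NA).
#'
#' @inheritParams scan_naive
#' @param Q an \code{admixture_q}.
#' @export
scan_q <- function(markers, y, Q, trait = "trait") {
  y <- .as_y(y, nrow(markers$scores))
  X0 <- cbind(rep(1, length(y)), .q_design(Q))
  .assoc_result(markers, .scan_core(markers$scores, y, X0), 2L, trait)
}

#' REML variance components under a kinship covariance (spectral profile)
#'
#' Fits \code{y = X_null b + g + e}, \code{g ~ MVN(0, sigma_g2 K)},
#' \code{e ~ MVN(0, sigma_e2 I)} by restricted maximum likelihood, profiling
#' the ratio \code{lambda = sigma_g2 / sigma_e2}. One eigendecomposition of K
#' rotates the problem so every lambda evaluation is O(n): a 100-point log
#' grid on [1e-5, 1e5] is refined by golden-section search. Boundary optima
#' are flagged, not errors.
#'
#' @param y numeric response.
#' @param X_null fixed-effect design (full column rank), e.g. intercept + Q.
#' @param K a \code{kinship_matrix} or square matrix, positive semidefinite
#'   (small negative eigenvalues within tolerance are clipped; larger ones
#'   are an error directing you to eigen-clip).
#' @return class \code{variance_components}: sigma_g2, sigma_e2, lambda,
#'   reml_loglik, boundary.
#' @export
fit_vc <- function(y, X_null, K) {
  Km <- if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
  n <- length(y)
  stopifnot(nrow(Km) == n, ncol(X_null) < n)
  e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  if (min(e$values) < -0.05 * max(abs(e$values)))
    stop("K is not positive semidefinite; eigen-clip it before fitting")
  d <- pmax(e$values, 0)  # tolerance clip: mild indefiniteness from negative
                          # truncation in the kinship estimator is zeroed
  yr <- crossprod(e$vectors, y)
  Xr <- crossprod(e$vectors, X_null)
  fit <- .fit_vc_rot(yr, Xr, d)
  structure(c(fit, list(eigen = e)), class = "variance_components")
}

# REML profile over lambda in the rotated (diagonal-covariance) space
.fit_vc_rot <- function(yr, Xr, d, grid_n = 100L) {
  n <- length(yr); p <- ncol(Xr)
  XtX <- crossprod(Xr)
  ldXtX <- determinant(XtX, logarithm = TRUE)$modulus
  ll <- function(loglam) {
    w <- exp(loglam) * d + 1
    XtWX <- crossprod(Xr, Xr / w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    XtWy <- crossprod(Xr, yr / w)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    rss <- max(sum(yr^2 / w) - sum(XtWy * beta), 1e-300)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
              2 * sum(log(diag(ch))) - ldXtX)
  }
  grid <- seq(log(1e-5), log(1e5), length.out = grid_n)
  lls <- vapply(grid, ll, 0)
  i <- which.max(lls)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, grid_n)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand_ll <- c(opt$objective, lls[i])
  cand_lam <- c(opt$maximum, grid[i])
  best <- which.max(cand_ll)
  lam <- exp(cand_lam[best])
  w <- lam * d + 1
  XtWX <- crossprod(Xr, Xr / w)
  ch <- chol(XtWX)
  XtWy <- crossprod(Xr, yr / w)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  rss <- max(sum(yr^2 / w) - sum(XtWy * beta), 0)
  s2e <- rss / (n - p)
  list(sigma_g2 = lam * s2e, sigma_e2 = s2e, lambda = lam,
       reml_loglik = cand_ll[best],
       boundary = i %in% c(1L, grid_n))
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components: sigma_g2 =", signif(x$sigma_g2, 4),
      " sigma_e2 =", signif(x$sigma_e2, 4),
      " lambda =", signif(x$lambda, 4),
      if (x$boundary) "(boundary)" else "", "\n")
  invisible(x)
}

#' Mixed-model scan with kinship covariance (models 3 and 4)
#'
#' Generalized least squares per marker under
#' \code{Var(y) = sigma_g2 K + sigma_e2 I}, Wald t/F test of the marker
#' effect with denominator df \code{n - rank(X)}. Model 3 omits Q, model 4
#' (the Q+K method) includes it. \code{vc_strategy = "null-once"} estimates
#' the variance components once from the marker-free null model and reuses
#' them for every marker (fast, the default); \code{"per-marker"} re-profiles
#' REML with each marker in the design (the exact route, used by the oracle
#' tests).
#'
#' @inheritParams scan_q
#' @param K a \code{kinship_matrix}.
#' @param Q optional \code{admixture_q}; supplying it makes this model 4.
#' @param vc_strategy \code{"null-once"} or \code{"per-marker"}.
#' @return an \code{assoc_scan} with attribute \code{vc} (the null-model
#'   variance components).
#' @export
scan_mixed <- function(markers, y, K, Q = NULL,
                       vc_strategy = c("null-once", "per-marker"),
                       trait = "trait") {
  vc_strategy <- match.arg(vc_strategy)
  y <- .as_y(y, nrow(markers$scores))
  n <- length(y)
  X0 <- cbind(rep(1, length(y)), .q_design(Q))
  Km <- if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
  e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  if (min(e$values) < -0.05 * max(abs(e$values)))
    stop("K is not positive semidefinite; eigen-clip it before scanning")
  d <- pmax(e$values, 0)
  U <- e$vectors
  yr <- crossprod(U, y); Xr0 <- crossprod(U, X0)
  Mr <- crossprod(U, markers$scores)
  vc0 <- .fit_vc_rot(yr, Xr0, d)
  model_id <- if (is.null(Q)) 3L else 4L
  if (vc_strategy == "null-once") {
    sw <- sqrt(vc0$lambda * d + 1)
    ys <- yr / sw; X0s <- Xr0 / sw; Ms <- Mr / sw
    ones <- crossprod(U, rep(1, n)) / sw
    tss <- sum(qr.resid(qr(ones), ys)^2)
    core <- .scan_core_mat(Ms, ys, X0s, tss, colnames(markers$scores),
                           raw_scores = markers$scores)
    return(.assoc_result(markers, core, model_id, trait,
                         extra = list(vc = vc0, vc_strategy = vc_strategy)))
  }
  # per-marker REML
  m <- ncol(Mr)
  effect <- stat <- p <- r2 <- rep(NA_real_, m)
  df <- n - ncol(X0) - 1L
  cs <- colSums(scale(markers$scores, center = TRUE, scale = FALSE)^2)
  for (j in seq_len(m)) {
    if (cs[j] == 0) next
    Xj <- cbind(Xr0, Mr[, j])
    if (qr(Xj)$rank < ncol(Xj)) next
    fit <- .fit_vc_rot(yr, Xj, d)
    w <- fit$lambda * d + 1
    XtWX <- crossprod(Xj, Xj / w)
    ch <- chol(XtWX)
    XtWy <- crossprod(Xj, yr / w)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    rss <- max(sum(yr^2 / w) - sum(XtWy * beta), 0)
    s2 <- rss / (n - ncol(Xj))
    covb <- chol2inv(ch) * s2
    effect[j] <- beta[length(beta)]
    se <- sqrt(covb[ncol(Xj), ncol(Xj)])
    stat[j] <- effect[j] / se
    p[j] <- pmax(2 * stats::pt(-abs(stat[j]), n - ncol(Xj)),
                 .Machine$double.xmin)
    # GLS incremental R^2 at this marker's lambda
    XtW0 <- crossprod(Xr0, Xr0 / w)
    b0 <- solve(XtW0, crossprod(Xr0, yr / w))
    rss0 <- max(sum(yr^2 / w) - sum(crossprod(Xr0, yr / w) * b0), 0)
    onesr <- crossprod(U, rep(1, n))
    bI <- sum(onesr * yr / w) / sum(onesr^2 / w)
    tss <- sum(yr^2 / w) - bI^2 * sum(onesr^2 / w)
    r2[j] <- if (tss > 0) max(min((rss0 - rss) / tss, 1), 0) else NA_real_
  }
  core <- list(effect = effect, stat = stat, df = df, p = p, r2 = r2)
  .assoc_result(markers, core, model_id, trait,
                extra = list(vc = vc0, vc_strategy = vc_strategy))
}

# scan on an already-transformed marker matrix; testability judged on the
# raw binary scores (monomorphic/collinear detection)
.scan_core_mat <- function(Ms, ys, X0s, tss, marker_names, raw_scores) {
  n <- length(ys)
  qr0 <- qr(X0s)
  My <- qr.resid(qr0, ys)
  MX <- qr.resid(qr0, Ms)
  sxx <- colSums(MX^2)
  cs <- colSums(scale(raw_scores, center = TRUE, scale = FALSE)^2)
  ref <- colSums(Ms^2)
  testable <- cs > 0 & sxx > pmax(ref, .Machine$double.eps) * 1e-9
  rss0 <- sum(My^2)
  sxy <- as.numeric(crossprod(MX, My))
  df <- n - ncol(X0s) - 1L
  beta <- ifelse(testable, sxy / sxx, NA_real_)
  rss1 <- pmax(rss0 - ifelse(testable, sxy^2 / sxx, 0), 0)
  se <- sqrt(rss1 / df / sxx)
  stat <- ifelse(testable & se > 0, beta / se, ifelse(testable, Inf, NA_real_))
  p <- ifelse(is.na(stat), NA_real_,
              pmax(2 * stats::pt(-abs(stat), df), .Machine$double.xmin))
  r2 <- ifelse(testable, pmax((rss0 - rss1) / tss, 0), NA_real_)
  list(effect = beta, stat = stat, df = df, p = p, r2 = pmin(r2, 1),
       rss0 = rss0, tss = tss)
}

#' Variance explained by the marker term of a scan
#'
#' Incremental R^2 of the marker relative to the same model without it; on
#' the generalized-least-squares (whitened) scale for the mixed models.
#' Clamped to [0, 1].
#'
#' @param scan an \code{assoc_scan}.
#' @return numeric vector, one fraction per marker.
#' @export
variance_explained <- function(scan) {
  stopifnot(inherits(scan, "assoc_scan"))
  scan$r2
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; markers flagged untestable (NA) are left NA and
#' excluded from the family size.
#'
#' @param p raw p-values in (0, 1] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Step-down maxT resampling adjustment
#'
#' Westfall-Young step-down maxT: the response is permuted (for the mixed
#' models, the null-model residuals are permuted in the whitened space where
#' errors are exchangeable, then recombined with the null fit), every marker
#' is rescanned, and the adjusted p of marker j is the fraction of
#' permutations in which the maximum |t| over the step-down set reaches its
#' observed |t|, with monotonicity enforced. The +1/(B+1) estimator avoids
#' zero p-values.
#'
#' @inheritParams scan_naive
#' @param model model id 1-4 (decides which covariates/whitening apply).
#' @param Q,K covariates for models 2-4.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer seed; adjusted p-values are bitwise reproducible.
#' @return numeric vector of adjusted p-values (NA for untestable markers)
#'   with attribute \code{p_perm_raw} (per-marker unadjusted permutation p).
#' @export
adjust_resampling <- function(markers, y, model = 1L, Q = NULL, K = NULL,
                              n_perm = 500L, seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100 gives coarse adjusted p-values")
  y <- .as_y(y, nrow(markers$scores))
  n <- length(y)
  X0 <- cbind(rep(1, length(y)), if (model %in% c(2L, 4L)) .q_design(Q))
  if (model %in% c(3L, 4L)) {
    stopifnot(!is.null(K))
    Km <- if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
    e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
    d <- pmax(e$values, 0)
    yr <- crossprod(e$vectors, y); Xr0 <- crossprod(e$vectors, X0)
    vc0 <- .fit_vc_rot(yr, Xr0, d)
    sw <- sqrt(vc0$lambda * d + 1)
    ys <- as.numeric(yr / sw); X0w <- Xr0 / sw
    Mw <- crossprod(e$vectors, markers$scores) / sw
  } else {
    ys <- y; X0w <- X0; Mw <- markers$scores
  }
  qr0 <- qr(X0w)
  My <- qr.resid(qr0, ys)
  MX <- qr.resid(qr0, Mw)
  sxx <- colSums(MX^2)
  cs <- colSums(scale(markers$scores, center = TRUE, scale = FALSE)^2)
  testable <- cs > 0 & sxx > pmax(colSums(Mw^2), .Machine$double.eps) * 1e-9
  df <- n - ncol(X0w) - 1L
  rss0 <- sum(My^2)
  sxy <- as.numeric(crossprod(MX, My))
  tobs <- abs(sxy / sqrt(sxx)) * sqrt(df) /
    sqrt(pmax(rss0 - sxy^2 / sxx, 1e-300))
  tobs[!testable] <- NA
  # permutations of the (whitened) null residuals recombined with the null fit
  fit0 <- qr.fitted(qr0, ys)
  set.seed(seed)
  B <- as.integer(n_perm)
  Eperm <- vapply(seq_len(B), function(b) fit0 + My[sample.int(n)], numeric(n))
  ME <- qr.resid(qr0, Eperm)
  SXY <- crossprod(MX, ME)                      # m x B
  rss0b <- colSums(ME^2)
  Tb <- abs(SXY / sqrt(sxx)) * sqrt(df) /
    sqrt(pmax(sweep(-SXY^2 / sxx, 2L, rss0b, "+"), 1e-300))
  Tb[!testable, ] <- -Inf
  # step-down maxT over testable markers, ordered by decreasing observed |t|
  idx <- which(testable)
  ord <- idx[order(-tobs[idx])]
  succ <- matrix(0, length(ord), B)
  run_max <- rep(-Inf, B)
  for (r in rev(seq_along(ord))) {
    run_max <- pmax(run_max, Tb[ord[r], ])
    succ[r, ] <- run_max >= tobs[ord[r]]
  }
  padj <- (1 + rowSums(succ)) / (B + 1)
  padj <- cummax(padj)                          # enforce monotone step-down
  out <- rep(NA_real_, length(tobs))
  out[ord] <- padj
  praw <- rep(NA_real_, length(tobs))
  praw[idx] <- vapply(idx, function(j) (1 + sum(Tb[j, ] >= tobs[j])) / (B + 1), 0)
  attr(out, "p_perm_raw") <- praw
  out
}

#' Per-subpopulation trait summaries: one-way ANOVA and LSD comparisons
#'
#' For each trait: a one-way ANOVA across subpopulation labels, plus pairwise
#' least-significant-difference flags
#' \code{LSD = t(1 - alpha/2, df_e) * sqrt(MSE (1/n_i + 1/n_j))}. Groups with
#' fewer than 2 members are dropped with a warning.
#'
#' @param phenos a \code{phenotype_table}.
#' @param labels per-accession group labels (e.g. from
#'   \code{\link{assign_members}}).
#' @param alpha LSD significance level (default 0.05).
#' @return list with data.frames \code{anova} (trait, F, df1, df2, p) and
#'   \code{lsd} (trait, group pair, mean difference, lsd, significant).
#' @export
summarize_subpops <- function(phenos, labels, alpha = 0.05) {
  stopifnot(inherits(phenos, "phenotype_table"))
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("dropping group(s) with < 2 members: ", paste(small, collapse = ", "))
    keep <- !(labels %in% small)
  } else keep <- rep(TRUE, length(labels))
  g <- factor(labels[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups with >= 2 members")
  Y <- phenos$values[keep, , drop = FALSE]
  an <- list(); ls <- list()
  for (tr in colnames(Y)) {
    yv <- Y[, tr]
    fit <- stats::lm(yv ~ g)
    a <- stats::anova(fit)
    mse <- a[["Mean Sq"]][2L]; dfe <- a$Df[2L]
    an[[tr]] <- data.frame(trait = tr, F = a$F[1L], df1 = a$Df[1L],
                           df2 = dfe, p = a$`Pr(>F)`[1L])
    mns <- tapply(yv, g, mean); ns <- tapply(yv, g, length)
    cmb <- utils::combn(levels(g), 2L)
    lsd <- stats::qt(1 - alpha / 2, dfe) *
      sqrt(mse * (1 / ns[cmb[1L, ]] + 1 / ns[cmb[2L, ]]))
    dif <- mns[cmb[1L, ]] - mns[cmb[2L, ]]
    ls[[tr]] <- data.frame(trait = tr, group1 = cmb[1L, ], group2 = cmb[2L, ],
                           diff = as.numeric(dif), lsd = as.numeric(lsd),
                           significant = abs(dif) > lsd, row.names = NULL)
  }
  list(anova = do.call(rbind, c(an, list(make.row.names = FALSE))),
       lsd = do.call(rbind, c(ls, list(make.row.names = FALSE))))
}

#' Write an association scan as TSV
#' @param scan an \code{assoc_scan}; \code{path} output file.
#' @param path file path.
#' @export
write_assoc_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
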