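#' Admixture membership matrix
#'
#' Accessions x subpopulations membership probabilities; every row sums to 1.
#' Produced by \code{\link{simulate_population}} (ground truth) or
#' \code{\link{estimate_admixture}} (posterior mean), and consumed as fixed
#' covariates by the structure-corrected association models.
#'
#' @param memberships accessions x K matrix in [0,1], rows summing to 1.
#' @param loglik_trace optional per-iteration data log-likelihood values.
#' @export
admixture_q <- function(memberships, loglik_trace = NULL) {
  m <- as.matrix(memberships)
  if (any(m < -1e-12) || any(abs(rowSums(m) - 1) > 1e-9))
    stop("membership rows must be probabilities summing to 1")
  structure(list(memberships = m, K = ncol(m), loglik_trace = loglik_trace),
            class = "admixture_q")
}

#' @export
print.admixture_q <- function(x, ...) {
  cat("admixture_q:", nrow(x$memberships), "accessions x", x$K, "subpopulations\n")
  invisible(x)
}

# accept either an admixture_q or a bare matrix
unclass_q <- function(Q) {
  if (inherits(Q, "admixture_q")) Q$memberships else as.matrix(Q)
}

#' Jaccard distance between accessions from binary marker profiles
#'
#' d(i,j) = 1 - |A intersect B| / |A union B| over the sets of present bands.
#' Shared absences carry no information for dominant markers, which is why
#' Jaccard rather than simple matching is the field's default here.
#'
#' @param markers a \code{marker_matrix}.
#' @return object of class \code{distance_matrix}: list with \code{values}
#'   (symmetric, zero diagonal) and \code{metric}.
#' @export
jaccard_distance <- function(markers) {
  S <- markers$scores
  rs <- rowSums(S)
  if (any(rs == 0))
    stop("accession(s) with all-zero profile: ",
         paste(rownames(S)[rs == 0], collapse = ", "),
         " (Jaccard undefined)")
  inter <- tcrossprod(S)
  union <- outer(rs, rs, "+") - inter
  d <- 1 - inter / union
  diag(d) <- 0
  structure(list(values = d, metric = "jaccard"), class = "distance_matrix")
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes; coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Axes with
#' negative eigenvalues are dropped and their total magnitude reported.
#'
#' @param dist a \code{distance_matrix} (or square symmetric matrix).
#' @param n_axes number of axes requested.
#' @return class \code{pco_result}: \code{coordinates}, \code{eigenvalues}
#'   (non-increasing, positive ones retained), \code{variance_fraction},
#'   \code{negative_mass}.
#' @export
pco <- function(dist, n_axes = 2L) {
  D <- if (inherits(dist, "distance_matrix")) dist$values else as.matrix(dist)
  n <- nrow(D)
  B <- -0.5 * D^2
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))  # row+col sweep == -0.5 J D^2 J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12 & e$values > 0
  n_pos <- sum(pos)
  if (n_axes > n_pos) {
    warning("only ", n_pos, " positive-eigenvalue axes available; truncating")
    n_axes <- n_pos
  }
  ev <- e$values[seq_len(n_pos)]
  coords <- e$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_axes)]), n_axes)
  rownames(coords) <- rownames(D)
  colnames(coords) <- sprintf("PCo%d", seq_len(n_axes))
  structure(list(coordinates = coords, eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 negative_mass = sum(abs(e$values[e$values < 0]))),
            class = "pco_result")
}

#' Kernel-density mode clustering in principal-coordinate space
#'
#' A model-free alternative to Bayesian clustering: estimate a Gaussian-kernel
#' density at every accession in the retained PCO axes, then hill-climb — each
#' point joins its highest-density neighbour within one bandwidth radius, and
#' points with no denser neighbour seed clusters, numbered in decreasing order
#' of their mode density. Cluster stability is a bootstrap co-assignment
#' fraction in [0,1] (replacing a parametric significance test).
#'
#' @param pco a \code{pco_result}.
#' @param n_axes_used number of leading axes to cluster in (default 2).
#' @param bandwidth positive scalar or \code{"auto"} (Silverman-style rule on
#'   the retained axes).
#' @param stability_reps bootstrap replicates for the stability score.
#' @param seed seed for the bootstrap.
#' @return class \code{cluster_result}: \code{labels}, \code{n_clusters},
#'   \code{densities}, \code{stability}, \code{bandwidth}.
#' @export
modeclus <- function(pco, n_axes_used = 2L, bandwidth = "auto",
                     stability_reps = 25L, seed = 1L) {
  X <- pco$coordinates[, seq_len(min(n_axes_used, ncol(pco$coordinates))),
                       drop = FALSE]
  n <- nrow(X); d <- ncol(X)
  if (identical(bandwidth, "auto")) {
    sds <- apply(X, 2L, stats::sd)
    h <- exp(mean(log(pmax(sds, 1e-12)))) * (4 / (d + 2))^(1 / (d + 4)) *
      n^(-1 / (d + 4))
  } else {
    h <- bandwidth
    if (!is.numeric(h) || h <= 0) stop("bandwidth must be positive or 'auto'")
  }
  # collapse coincident points: duplicates always share a label
  key <- apply(round(X / max(1e-12, h) * 1e9), 1L, paste, collapse = "|")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  U <- X[uniq, , drop = FALSE]
  # order-invariance: operate on lexicographically sorted unique points
  ord <- do.call(order, as.data.frame(U))
  U <- U[ord, , drop = FALSE]
  lab_u <- .modeclus_core(U, h)
  labs <- integer(n)
  labs[uniq] <- lab_u$labels[order(ord)]
  labs <- labs[map]
  dens <- numeric(n)
  dens[uniq] <- lab_u$density[order(ord)]
  dens <- dens[map]
  ncl <- lab_u$n_clusters
  if (ncl == n) warning("every point is its own mode; bandwidth likely too small")
  # bootstrap stability: fraction of member pairs co-assigned across resamples
  set.seed(seed)
  members <- split(seq_len(n), labs)
  hits <- num <- numeric(ncl)
  for (b in seq_len(stability_reps)) {
    idx <- sort(unique(sample.int(n, n, replace = TRUE)))
    Xb <- X[idx, , drop = FALSE]
    kb <- apply(round(Xb / max(1e-12, h) * 1e9), 1L, paste, collapse = "|")
    ub <- !duplicated(kb); mb <- match(kb, kb[ub])
    Ub <- Xb[ub, , drop = FALSE]
    ob <- do.call(order, as.data.frame(Ub))
    lb_u <- .modeclus_core(Ub[ob, , drop = FALSE], h)$labels[order(ob)]
    lb <- lb_u[mb]
    for (c in seq_len(ncl)) {
      pres <- match(members[[c]], idx)
      pres <- pres[!is.na(pres)]
      if (length(pres) >= 2L) {
        lc <- lb[pres]
        tab <- table(lc)
        same <- sum(tab * (tab - 1)) / 2
        tot <- length(pres) * (length(pres) - 1) / 2
        hits[c] <- hits[c] + same
        num[c] <- num[c] + tot
      }
    }
  }
  stab <- ifelse(num > 0, hits / pmax(num, 1), 1)
  structure(list(labels = labs, n_clusters = ncl, densities = dens,
                 stability = as.numeric(stab), bandwidth = h),
            class = "cluster_result")
}

# hill-climbing mode clustering on unique points (rows assumed sorted)
.modeclus_core <- function(U, h) {
  nu <- nrow(U)
  D2 <- as.matrix(stats::dist(U))^2
  dens <- rowMeans(exp(-D2 / (2 * h^2)))
  parent <- integer(nu)
  for (i in seq_len(nu)) {
    nb <- which(D2[i, ] <= h^2 & dens > dens[i] + 1e-15)
    parent[i] <- if (length(nb)) nb[which.max(dens[nb])] else i
  }
  root <- seq_len(nu)
  for (i in seq_len(nu)) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    root[i] <- r
  }
  modes <- sort(unique(root))
  modes <- modes[order(-dens[modes])]  # cluster 1 = densest mode
  labels <- match(root, modes)
  list(labels = labels, density = dens, n_clusters = length(modes))
}

#' Bayesian admixture estimation for haploid dominant markers
#'
#' A Gibbs sampler for the independent-allele-frequency admixture model:
#' latent per-accession-per-marker ancestries z, Beta(1,1) priors on
#' subpopulation band frequencies, a flat Dirichlet prior on memberships, and
#' a Bernoulli likelihood for the observed bands. The posterior mean of Q is
#' accumulated after burn-in with greedy label alignment against the first
#' retained sample (label switching).
#'
#' @param markers a \code{marker_matrix}.
#' @param K assumed number of subpopulations.
#' @param n_iter total Gibbs iterations (default 3000).
#' @param burnin discarded iterations (default 1000).
#' @param seed integer seed.
#' @return an \code{\link{admixture_q}} with the log-likelihood trace.
#' @export
estimate_admixture <- function(markers, K, n_iter = 3000L, burnin = 1000L,
                               seed = 1L) {
  stopifnot(inherits(markers, "marker_matrix"), K >= 1)
  if (n_iter <= burnin) stop("n_iter must exceed burnin")
  n <- nrow(markers$scores)
  if (K == 1L) {
    Q <- matrix(1, n, 1L, dimnames = list(rownames(markers$scores), "pop1"))
    ll <- .admix_loglik_k1(markers$scores)
    return(admixture_q(Q, loglik_trace = rep(ll, n_iter - burnin)))
  }
  set.seed(seed)
  fit <- gibbs_admixture(markers$scores, as.integer(K), as.integer(n_iter),
                         as.integer(burnin))
  Q <- fit$Q
  rownames(Q) <- rownames(markers$scores)
  colnames(Q) <- sprintf("pop%d", seq_len(K))
  Q <- Q / rowSums(Q)
  admixture_q(Q, loglik_trace = as.numeric(fit$loglik))
}

# saturated K=1 log-likelihood: Bernoulli at posterior-mean frequencies
.admix_loglik_k1 <- function(S) {
  p <- (colSums(S) + 1) / (nrow(S) + 2)
  sum(S %*% log(p) + (1 - S) %*% log(1 - p))
}

#' Mean log-likelihood by assumed number of subpopulations
#'
#' Runs \code{\link{estimate_admixture}} over a K grid and reports the mean
#' post-burn-in data log-likelihood; no automatic K choice is made (the
#' criterion is left to the analyst).
#'
#' @param markers a \code{marker_matrix}.
#' @param k_range integer vector of K values (default 1:10).
#' @param replicates chains per K.
#' @param n_iter,burnin sampler settings.
#' @param seed base seed; replicate r of K uses \code{seed + 1000*K + r}.
#' @return data.frame with columns K, mean_loglik, sd_loglik.
#' @export
select_k <- function(markers, k_range = 1:10, replicates = 1L,
                     n_iter = 3000L, burnin = 1000L, seed = 1L) {
  stopifnot(length(k_range) >= 1)
  rows <- lapply(k_range, function(K) {
    ll <- vapply(seq_len(replicates), function(r) {
      q <- estimate_admixture(markers, K, n_iter, burnin,
                              seed = seed + 1000L * K + r)
      mean(q$loglik_trace[(burnin + 1):length(q$loglik_trace)], na.rm = TRUE)
    }, 0)
    data.frame(K = K, mean_loglik = mean(ll),
               sd_loglik = if (replicates > 1) stats::sd(ll) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Assign accessions to subpopulations by a membership threshold
#'
#' Argmax subpopulation when the maximum membership strictly exceeds the
#' threshold; otherwise \code{"admixed"}.
#'
#' @param Q an \code{admixture_q}.
#' @param threshold membership probability cutoff (default 0.70).
#' @return character vector of labels with a \code{counts} attribute.
#' @export
assign_members <- function(Q, threshold = 0.70) {
  m <- unclass_q(Q)
  if (is.null(colnames(m))) colnames(m) <- sprintf("pop%d", seq_len(ncol(m)))
  mx <- apply(m, 1L, max)
  arg <- max.col(m, ties.method = "first")
  lab <- ifelse(mx > threshold, colnames(m)[arg], "admixed")
  names(lab) <- rownames(m)
  attr(lab, "counts") <- table(factor(lab, levels = c(colnames(m), "admixed")))
  lab
}

#' Write an admixture Q matrix as TSV
#' @param Q an \code{admixture_q}; \code{path} output file.
#' @param path file path.
#' @export
write_admixture_q <- function(Q, path) {
  m <- unclass_q(Q)
  utils::write.table(data.frame(accession = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_admixture_q
#' @export
read_admixture_q <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  admixture_q(m / rowSums(m))
}
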