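#' Simulation configuration for a synthetic admixed collection
#'
#' Bundles every knob of the synthetic-data generator: an admixed population
#' of haploid, dominant-scored accessions with confounded quantitative traits
#' and known ground truth. Defaults emulate a diverse crop core collection:
#' 168 accessions, 4 subpopulations with a high level of admixture (Dirichlet
#' concentration 0.17, which puts about 65% of accessions above a 0.70
#' maximum-membership threshold), moderate divergence (Fst 0.25), and 11
#' correlated traits whose means differ by subpopulation.
#'
#' @param n_accessions number of accessions (rows).
#' @param n_subpops number of ancestral subpopulations (K >= 1).
#' @param fst divergence of subpopulation allele frequencies from the
#'   ancestral frequency, in (0,1); used as the Balding-Nichols F parameter.
#' @param admix_alpha symmetric Dirichlet concentration for per-accession
#'   membership rows; small values give near-pure accessions.
#' @param n_markers number of dominant binary markers.
#' @param causal_effects named numeric vector: names are marker column
#'   indices, values are effect sizes in phenotype-SD units. Empty by default.
#' @param pop_effects numeric vector of per-subpopulation phenotype shifts
#'   (SD units), recycled/zero-padded to \code{n_subpops}. Confounding source.
#' @param sigma_g2 polygenic variance; the random genotype effect has
#'   covariance \code{sigma_g2 * K}.
#' @param sigma_e2 residual variance.
#' @param n_traits number of traits in the phenotype table.
#' @param trait_corr residual correlation across traits: either a single
#'   AR(1)-chain coefficient rho (correlation rho^|i-j|) or a full
#'   \code{n_traits x n_traits} correlation matrix. Default 0.6.
#' @param seed integer seed making the whole generation deterministic.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_accessions = 168L, n_subpops = 4L, fst = 0.25,
                       admix_alpha = 0.17, n_markers = 250L,
                       causal_effects = numeric(0), pop_effects = 0,
                       sigma_g2 = 0, sigma_e2 = 1, n_traits = 1L,
                       trait_corr = 0.6, seed = 1L) {
  stopifnot(n_accessions >= 1, n_subpops >= 1, n_markers >= 1, n_traits >= 1)
  if (!(fst > 0 && fst < 1)) stop("fst must lie strictly in (0, 1)")
  if (admix_alpha <= 0) stop("admix_alpha must be > 0")
  if (sigma_g2 < 0 || sigma_e2 < 0) stop("variances must be >= 0")
  if (length(causal_effects) && is.null(names(causal_effects)))
    stop("causal_effects must be named by marker column index")
  ci <- as.integer(names(causal_effects))
  if (length(ci) && (any(is.na(ci)) || any(ci < 1L) || any(ci > n_markers)))
    stop("causal_effects index out of range 1..n_markers")
  pop_effects <- rep_len(as.numeric(pop_effects), n_subpops)
  if (is.matrix(trait_corr)) {
    stopifnot(nrow(trait_corr) == n_traits, ncol(trait_corr) == n_traits)
  } else {
    stopifnot(length(trait_corr) == 1L, abs(trait_corr) < 1)
  }
  structure(list(
    n_accessions = as.integer(n_accessions), n_subpops = as.integer(n_subpops),
    fst = fst, admix_alpha = admix_alpha, n_markers = as.integer(n_markers),
    causal_effects = causal_effects, pop_effects = pop_effects,
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, n_traits = as.integer(n_traits),
    trait_corr = trait_corr, seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_accessions, "accessions,", x$n_subpops,
      "subpops (fst", x$fst, ", alpha", x$admix_alpha, "),",
      x$n_markers, "markers,", x$n_traits, "traits,",
      length(x$causal_effects), "causal\n")
  invisible(x)
}

.acc_ids <- function(n) sprintf("acc%03d", seq_len(n))

#' Construct a dominant marker matrix
#'
#' @param scores accessions x markers matrix with values in \{0,1\}.
#' @param marker_types per-column type, \code{"AFLP"} or \code{"SSR"}.
#' @param ssr_locus per-column locus id for SSR-allele columns, NA otherwise.
#' @return object of class \code{marker_matrix}. \code{allele_freq} is always
#'   recomputed from the realized scores.
#' @export
marker_matrix <- function(scores, marker_types = NULL, ssr_locus = NULL) {
  scores <- as.matrix(scores)
  if (!all(scores %in% c(0, 1)))
    stop("marker scores must be strictly binary (0/1)")
  storage.mode(scores) <- "integer"
  if (is.null(rownames(scores))) rownames(scores) <- .acc_ids(nrow(scores))
  if (is.null(colnames(scores))) colnames(scores) <- sprintf("m%04d", seq_len(ncol(scores)))
  m <- ncol(scores)
  if (is.null(marker_types)) marker_types <- rep("AFLP", m)
  if (is.null(ssr_locus)) ssr_locus <- rep(NA_character_, m)
  stopifnot(length(marker_types) == m, length(ssr_locus) == m)
  if (any(marker_types == "SSR" & is.na(ssr_locus)))
    stop("SSR-allele columns must carry a locus id")
  structure(list(scores = scores, marker_types = as.character(marker_types),
                 ssr_locus = as.character(ssr_locus),
                 allele_freq = unname(colMeans(scores))),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$scores), "accessions x", ncol(x$scores),
      "markers (", sum(x$marker_types == "SSR"), "SSR-allele columns )\n")
  invisible(x)
}

#' @export
`[.marker_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$scores))
  if (missing(j)) j <- seq_len(ncol(x$scores))
  if (is.character(j)) j <- match(j, colnames(x$scores))
  if (is.logical(j)) j <- which(j)
  marker_matrix(x$scores[i, j, drop = FALSE], x$marker_types[j], x$ssr_locus[j])
}

#' @export
dim.marker_matrix <- function(x) dim(x$scores)

#' Construct a phenotype table
#' @param values accessions x traits numeric matrix (finite).
#' @param units free-text unit label.
#' @export
phenotype_table <- function(values, units = "") {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("phenotype values must be finite")
  if (is.null(rownames(values))) rownames(values) <- .acc_ids(nrow(values))
  if (is.null(colnames(values))) colnames(values) <- sprintf("trait%02d", seq_len(ncol(values)))
  structure(list(values = values, units = units), class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table:", nrow(x$values), "accessions x", ncol(x$values), "traits\n")
  invisible(x)
}

#' Simulate subpopulation allele frequencies and admixture proportions
#'
#' Ancestral allele frequencies are drawn uniform on [0.1, 0.9] (avoiding
#' near-fixed loci); each subpopulation frequency is a Balding-Nichols draw
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral p with divergence F;
#' each accession's membership row is Dirichlet(admix_alpha).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{Q} (an \code{admixture_q}) and
#'   \code{subpop_allele_freqs} (subpops x markers matrix in [0,1]).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_subpops; m <- cfg$n_markers; n <- cfg$n_accessions
  p_anc <- stats::runif(m, 0.1, 0.9)
  f <- cfg$fst
  P <- matrix(stats::rbeta(K * m, rep(p_anc, each = K) * (1 - f) / f,
                           rep(1 - p_anc, each = K) * (1 - f) / f), K, m)
  if (K == 1L) {
    Q <- matrix(1, n, 1L)
  } else {
    g <- matrix(stats::rgamma(n * K, shape = cfg$admix_alpha), n, K)
    # guard against all-zero gamma rows at tiny alpha (underflow)
    zero <- rowSums(g) == 0
    if (any(zero)) g[zero, ] <- t(stats::rmultinom(sum(zero), 1L, rep(1, K)))
    Q <- g / rowSums(g)
  }
  rownames(Q) <- .acc_ids(n)
  colnames(Q) <- sprintf("pop%d", seq_len(K))
  rownames(P) <- colnames(Q)
  colnames(P) <- sprintf("m%04d", seq_len(m))
  list(Q = admixture_q(Q), subpop_allele_freqs = P)
}

#' Simulate dominant binary marker scores
#'
#' Marker j of accession i is Bernoulli with success probability
#' \code{sum_k Q[i,k] * P[k,j]} — a haploid dominant band drawn from the
#' accession's mixed ancestry.
#'
#' @param Q an \code{admixture_q} (rows sum to 1).
#' @param subpop_allele_freqs subpops x markers frequency matrix.
#' @param n_markers optional: use only the first \code{n_markers} columns.
#' @param seed integer seed.
#' @return a \code{\link{marker_matrix}}; \code{allele_freq} is recomputed
#'   from the realized scores.
#' @export
simulate_markers <- function(Q, subpop_allele_freqs, n_markers = ncol(subpop_allele_freqs),
                             seed = 1L) {
  Qm <- unclass_q(Q)
  P <- as.matrix(subpop_allele_freqs)
  if (ncol(Qm) != nrow(P)) stop("Q columns and frequency-matrix rows disagree")
  if (n_markers > ncol(P)) stop("n_markers exceeds frequency-matrix columns")
  P <- P[, seq_len(n_markers), drop = FALSE]
  set.seed(seed)
  prob <- Qm %*% P
  sc <- matrix(as.integer(stats::runif(length(prob)) < prob), nrow(prob), ncol(prob))
  rownames(sc) <- rownames(Qm); colnames(sc) <- colnames(P)
  marker_matrix(sc)
}

# eigen-clip a kinship matrix to PSD; returns list(mat, clip = total negative mass)
.psd_clip <- function(K) {
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  neg <- e$values < 0
  clip <- sum(abs(e$values[neg]))
  if (clip > 0) {
    v <- pmax(e$values, 0)
    K <- e$vectors %*% (v * t(e$vectors))
    K <- (K + t(K)) / 2
  }
  list(mat = K, clip = clip, eig = e)
}

#' Simulate phenotypes with population, marker, polygenic and noise terms
#'
#' Generates \code{y = Q \%*\% pop_effects + X_causal \%*\% beta + g + e} per
#' trait, with \code{g ~ MVN(0, sigma_g2 K)} (K eigen-clipped to positive
#' semidefinite if needed; the clipped mass is recorded) and residuals
#' correlated across traits according to \code{cfg$trait_corr}. Marker and
#' population terms are shared across traits; polygenic and residual draws
#' are trait-specific. All four components are stored per accession and trait
#' and sum to the phenotype exactly.
#'
#' @param markers a \code{marker_matrix}.
#' @param Q an \code{admixture_q}.
#' @param K a kinship matrix (square, symmetric).
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{phenotypes} (a \code{phenotype_table}) and
#'   \code{truth} (class \code{sim_truth}): components \code{pop},
#'   \code{marker}, \code{polygenic}, \code{noise} (each n x traits),
#'   \code{causal_markers}, and \code{psd_clip}.
#' @export
simulate_phenotypes <- function(markers, Q, K, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(markers, "marker_matrix"))
  Qm <- unclass_q(Q)
  Km <- if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
  n <- nrow(markers$scores)
  stopifnot(nrow(Qm) == n, nrow(Km) == n, ncol(Km) == n)
  set.seed(cfg$seed + 1L)
  t_ <- cfg$n_traits
  pop <- matrix(rep(Qm %*% cfg$pop_effects, t_), n, t_)
  ci <- as.integer(names(cfg$causal_effects))
  mk <- if (length(ci)) {
    matrix(rep(markers$scores[, ci, drop = FALSE] %*% cfg$causal_effects, t_), n, t_)
  } else matrix(0, n, t_)
  cl <- .psd_clip(Km)
  if (cfg$sigma_g2 > 0) {
    rt <- cl$eig$vectors %*% (sqrt(pmax(cl$eig$values, 0)) * t(cl$eig$vectors))
    g <- rt %*% matrix(stats::rnorm(n * t_), n, t_) * sqrt(cfg$sigma_g2)
  } else g <- matrix(0, n, t_)
  R <- if (is.matrix(cfg$trait_corr)) cfg$trait_corr else
    cfg$trait_corr^abs(outer(seq_len(t_), seq_len(t_), "-"))
  cR <- chol(R)
  eps <- matrix(stats::rnorm(n * t_), n, t_) %*% cR * sqrt(cfg$sigma_e2)
  y <- pop + mk + g + eps
  rownames(y) <- rownames(markers$scores)
  colnames(y) <- sprintf("trait%02d", seq_len(t_))
  dimnames(pop) <- dimnames(mk) <- dimnames(g) <- dimnames(eps) <- dimnames(y)
  truth <- structure(list(pop = pop, marker = mk, polygenic = g, noise = eps,
                          causal_markers = cfg$causal_effects,
                          psd_clip = cl$clip), class = "sim_truth")
  list(phenotypes = phenotype_table(y), truth = truth)
}

#' Binarize SSR genotype calls into per-allele dominant columns
#'
#' Converts multi-allelic microsatellite calls to one binary presence/absence
#' column per distinct observed allele, grouped by locus — the standard way to
#' fold codominant SSRs into a dominant-marker pipeline.
#'
#' @param calls long-format data.frame with columns \code{accession},
#'   \code{locus}, \code{allele}; one row per allele carried.
#' @param accessions optional accession universe (default: unique order of
#'   appearance).
#' @return a \code{\link{marker_matrix}} of SSR-allele columns named
#'   \code{<locus>_<allele>}.
#' @export
binarize_ssr <- function(calls, accessions = NULL) {
  stopifnot(all(c("accession", "locus", "allele") %in% names(calls)))
  if (is.null(accessions)) accessions <- unique(as.character(calls$accession))
  loci <- unique(as.character(calls$locus))
  cols <- list(); types <- character(0); locus_of <- character(0)
  for (lc in loci) {
    sub <- calls[as.character(calls$locus) == lc, , drop = FALSE]
    if (nrow(sub) == 0L) { warning("locus ", lc, " has no calls; skipped"); next }
    for (al in unique(as.character(sub$allele))) {
      carriers <- unique(as.character(sub$accession[as.character(sub$allele) == al]))
      cols[[paste0(lc, "_", al)]] <- as.integer(accessions %in% carriers)
      types <- c(types, "SSR"); locus_of <- c(locus_of, lc)
    }
  }
  if (!length(cols)) stop("no alleles observed")
  sc <- do.call(cbind, cols)
  rownames(sc) <- accessions
  marker_matrix(sc, types, locus_of)
}

#' Keep only the most frequent allele column of each SSR locus
#'
#' Avoids over-representation of multi-allelic loci in structure and kinship
#' analyses: for every SSR locus exactly the column with the highest allele
#' frequency is retained (ties broken by first column order); non-SSR columns
#' pass through unchanged.
#'
#' @param markers a \code{marker_matrix}.
#' @return a \code{marker_matrix} with one column per SSR locus.
#' @export
most_frequent_allele_subset <- function(markers) {
  stopifnot(inherits(markers, "marker_matrix"))
  keep <- rep(TRUE, ncol(markers$scores))
  for (lc in unique(stats::na.omit(markers$ssr_locus))) {
    idx <- which(markers$ssr_locus == lc & markers$marker_types == "SSR")
    if (length(idx) <= 1L) next
    best <- idx[which.max(markers$allele_freq[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  markers[, keep]
}

#' Filter markers by allele frequency
#'
#' Retains marker j iff \code{min_freq < allele_freq[j] < 1 - min_freq}
#' (strict on both sides). The symmetric upper cut removes near-monomorphic
#' "present in all" bands, for which single-marker tests are as uninformative
#' as for rare ones.
#'
#' @param markers a \code{marker_matrix}.
#' @param min_freq lower frequency bound (default 0.10).
#' @return filtered \code{marker_matrix} with attributes \code{n_kept} and
#'   \code{n_dropped}.
#' @export
filter_markers <- function(markers, min_freq = 0.10) {
  stopifnot(inherits(markers, "marker_matrix"), min_freq >= 0, min_freq < 0.5)
  keep <- markers$allele_freq > min_freq & markers$allele_freq < 1 - min_freq
  if (!any(keep)) stop("no markers pass frequency filter")
  out <- markers[, keep]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

## ---- delimited-text I/O ----------------------------------------------------

#' Write / read a marker matrix as TSV
#'
#' Layout: first column \code{accession}, then one column per marker with
#' values in \{0,1\}; a sidecar \code{<path>.meta.tsv} stores marker name,
#' type and SSR locus. The round trip is lossless.
#'
#' @param markers a \code{marker_matrix}.
#' @param path output file path (TSV).
#' @export
write_marker_matrix <- function(markers, path) {
  stopifnot(inherits(markers, "marker_matrix"))
  df <- data.frame(accession = rownames(markers$scores), markers$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(marker = colnames(markers$scores),
                     type = markers$marker_types, locus = markers$ssr_locus)
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_matrix
#' @export
read_marker_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicated accession id: ",
                               ids[duplicated(ids)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!(vals %in% c("0", "1")), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(vals))
    stop(sprintf("non-binary or missing value '%s' at row %d (%s), column %d (%s)",
                 vals[bad[1L]], rc[1], ids[rc[1]], rc[2], colnames(vals)[rc[2]]))
  }
  sc <- matrix(as.integer(vals), nrow(vals), ncol(vals),
               dimnames = list(ids, colnames(vals)))
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, colClasses = "character")
    meta <- meta[match(colnames(sc), meta$marker), ]
    marker_matrix(sc, meta$type, ifelse(meta$locus == "NA", NA, meta$locus))
  } else marker_matrix(sc)
}

#' Write / read a phenotype table as TSV
#' @param phenos a \code{phenotype_table}.
#' @param path file path.
#' @export
write_phenotype_table <- function(phenos, path) {
  stopifnot(inherits(phenos, "phenotype_table"))
  df <- data.frame(accession = rownames(phenos$values), phenos$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated accession id: ",
                               ids[duplicated(ids)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || any(is.na(vals)))
    stop("phenotype table contains non-numeric or missing cells")
  rownames(vals) <- ids
  phenotype_table(vals)
}

#' Serialize simulation ground truth to a directory of TSVs
#'
#' Writes the component matrices, causal effects and a key-value config echo;
#' everything needed to audit a synthetic dataset from disk.
#' @param truth a \code{sim_truth}.
#' @param cfg the generating \code{sim_config}.
#' @param dir output directory (created).
#' @export
write_sim_truth <- function(truth, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("pop", "marker", "polygenic", "noise")) {
    utils::write.table(data.frame(accession = rownames(truth[[nm]]), truth[[nm]],
                                  check.names = FALSE),
                       file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  ce <- truth$causal_markers
  utils::write.table(data.frame(marker_index = names(ce), effect = as.numeric(ce)),
                     file.path(dir, "causal.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  scl <- vapply(cfg[setdiff(names(cfg), c("causal_effects", "trait_corr", "pop_effects"))],
                function(v) paste(v, collapse = ","), "")
  writeLines(c(paste0(names(scl), ": ", scl),
               paste0("pop_effects: ", paste(cfg$pop_effects, collapse = ",")),
               paste0("psd_clip: ", truth$psd_clip)),
             file.path(dir, "config.yml"))
  invisible(dir)
}
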