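#' Kinship matrix container
#'
#' Symmetric accessions x accessions relatedness coefficients on a similarity
#' scale: off-diagonals truncated to [0,1], unit diagonal. With this
#' convention the polygenic variance sigma_g2 in \code{V_G = sigma_g2 * K} is
#' the genotypic variance of a single non-inbred accession.
#'
#' @param values square symmetric matrix.
#' @param estimator label of the producing estimator.
#' @export
kinship_matrix <- function(values, estimator = "unknown") {
  v <- as.matrix(values)
  stopifnot(nrow(v) == ncol(v))
  if (max(abs(v - t(v))) > 1e-8) stop("kinship matrix must be symmetric")
  v <- (v + t(v)) / 2
  structure(list(values = v, estimator = estimator), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  od <- x$values[upper.tri(x$values)]
  cat("kinship_matrix (", x$estimator, "): ", nrow(x$values),
      " accessions, mean off-diagonal ", signif(mean(od), 3), "\n", sep = "")
  invisible(x)
}

#' Jaccard-similarity kinship
#'
#' K_ij = |A intersect B| / |A union B| over present bands; the complement of
#' \code{\link{jaccard_distance}}. Useful as a sanity alternative to the
#' frequency-corrected estimator.
#'
#' @param markers a \code{marker_matrix}.
#' @return a \code{\link{kinship_matrix}}.
#' @export
kinship_jaccard <- function(markers) {
  d <- jaccard_distance(markers)
  K <- 1 - d$values
  diag(K) <- 1
  kinship_matrix(K, "jaccard")
}

#' Frequency-corrected allele-sharing kinship
#'
#' For binary scores x and per-marker frequencies p, let
#' \deqn{A_{ik} = mean_j (x_{ij}-p_j)(x_{kj}-p_j) / (p_j (1-p_j))}
#' (average frequency-standardized allele sharing); the estimator is the
#' correlation-normalized form \code{K = A_ik / sqrt(A_ii A_kk)}, so two
#' identical profiles have kinship exactly 1. Negative values (less related
#' than random pairs) are truncated to 0 and the diagonal is set to 1, giving
#' the similarity-scale convention used by the mixed models. Requires
#' polymorphic markers — run \code{\link{filter_markers}} first.
#'
#' @param markers a \code{marker_matrix} with frequencies strictly in (0,1).
#' @param truncate truncate negatives to 0 (default TRUE; disable for
#'   diagnostics on the raw correlation scale).
#' @return a \code{\link{kinship_matrix}}.
#' @export
kinship_freq_corrected <- function(markers, truncate = TRUE) {
  p <- markers$allele_freq
  if (any(p <= 0 | p >= 1))
    stop("monomorphic marker present; apply filter_markers() first")
  Z <- sweep(markers$scores, 2L, p)
  Z <- sweep(Z, 2L, sqrt(p * (1 - p)), "/")
  A <- tcrossprod(Z) / ncol(Z)
  s <- 1 / sqrt(diag(A))
  K <- A * tcrossprod(s)
  if (truncate) K[K < 0] <- 0
  diag(K) <- 1
  kinship_matrix(K, "freqcorr")
}

#' Histogram of kinship coefficient classes
#'
#' Bins the off-diagonal upper-triangle kinship values into classes of width
#' \code{bin_width} starting at 0 and reports percentages (summing to 100).
#' A collection of mostly unrelated accessions shows a first-bin-dominant
#' profile.
#'
#' @param K a \code{kinship_matrix}.
#' @param bin_width class width (default 0.05).
#' @return data.frame with columns \code{lower}, \code{upper}, \code{percent}.
#' @export
kinship_histogram <- function(K, bin_width = 0.05) {
  v <- K$values[upper.tri(K$values)]
  v <- pmin(pmax(v, 0), 1)
  n_bins <- ceiling(1 / bin_width)
  cls <- pmin(floor(v / bin_width), n_bins - 1L)
  tab <- tabulate(cls + 1L, nbins = n_bins)
  data.frame(lower = bin_width * (seq_len(n_bins) - 1L),
             upper = bin_width * seq_len(n_bins),
             percent = 100 * tab / length(v))
}

#' Write / read a kinship matrix as TSV
#' @param K a \code{kinship_matrix}; \code{path} output file.
#' @param path file path.
#' @export
write_kinship <- function(K, path) {
  v <- K$values
  if (is.null(rownames(v))) rownames(v) <- .acc_ids(nrow(v))
  utils::write.table(data.frame(accession = rownames(v), v, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path, estimator = "file") {
  df <- utils::read.delim(path, check.names = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- as.character(df[[1L]])
  kinship_matrix(v, estimator)
}
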