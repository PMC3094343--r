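#' Full-order partial correlations between traits
#'
#' The correlation of each trait pair conditioning on all remaining traits:
#' scale the inverse of the correlation matrix,
#' \code{rho_ij.rest = -Omega_ij / sqrt(Omega_ii Omega_jj)}. P-values come
#' from the t transform with \code{df = n - 2 - k}, k the number of
#' conditioned traits. When the correlation matrix is near-singular (n close
#' to the trait count) the shrinkage method regularizes toward the identity
#' with an analytic intensity before inversion.
#'
#' @param phenos a \code{phenotype_table} (or numeric matrix).
#' @param method \code{"inverse"} (plain inversion, default) or
#'   \code{"shrinkage"}.
#' @return class \code{partial_corr}: \code{matrix} (unit diagonal,
#'   symmetric), \code{p}, \code{n}, \code{method}, \code{shrinkage_lambda}.
#' @export
partial_correlation <- function(phenos, method = c("inverse", "shrinkage")) {
  method <- match.arg(method)
  Y <- if (inherits(phenos, "phenotype_table")) phenos$values else as.matrix(phenos)
  n <- nrow(Y); p <- ncol(Y)
  if (p < 2L) stop("need at least 2 traits")
  R <- stats::cor(Y)
  lambda <- 0
  if (method == "inverse") {
    if (n <= p + 2L)
      stop("n <= n_traits + 2: use method = 'shrinkage'")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < max(ev) * 1e-10)
      stop("correlation matrix is singular; use method = 'shrinkage'")
  } else {
    lambda <- .shrinkage_intensity(Y, R)
    R <- (1 - lambda) * R
    diag(R) <- 1
  }
  Om <- solve(R)
  s <- 1 / sqrt(diag(Om))
  pc <- -Om * tcrossprod(s)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  df <- n - 2L - (p - 2L)
  if (df < 1L) stop("not enough samples for the partial-correlation test")
  tt <- pc * sqrt(df / pmax(1 - pc^2, 1e-300))
  pv <- 2 * stats::pt(-abs(tt), df)
  diag(pv) <- 0
  structure(list(matrix = pc, p = pv, n = n, method = method,
                 shrinkage_lambda = lambda, df = df),
            class = "partial_corr")
}

# Schafer-Strimmer analytic shrinkage intensity toward the identity target
.shrinkage_intensity <- function(Y, R) {
  n <- nrow(Y)
  Z <- scale(Y)
  num <- 0; den <- 0
  p <- ncol(Y)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    w <- Z[, i] * Z[, j]
    vr <- n / ((n - 1)^3) * sum((w - mean(w))^2)
    num <- num + vr
    den <- den + R[i, j]^2
  }
  min(1, max(0, if (den > 0) num / den else 1))
}

#' Build the metabolite-marker network
#'
#' Vertices are traits plus every marker significant after multiple-testing
#' adjustment; trait-trait edges connect pairs whose partial correlation has
#' p <= alpha (weight |rho|), marker-trait edges carry weight
#' \code{-log10(p_adj)}. Isolated trait vertices are retained; markers
#' without edges are dropped.
#'
#' @param pcorr a \code{\link{partial_correlation}} result.
#' @param scans an \code{assoc_scan}, or a list of them (one per trait), with
#'   \code{p_adj} filled in.
#' @param alpha edge significance level (default 0.05).
#' @return class \code{metabolite_network}: \code{vertices} (name, role) and
#'   \code{edges} (u, v, kind, weight) data.frames.
#' @export
build_network <- function(pcorr, scans, alpha = 0.05) {
  stopifnot(inherits(pcorr, "partial_corr"))
  if (inherits(scans, "assoc_scan")) scans <- list(scans)
  sc <- do.call(rbind, lapply(scans, function(s)
    as.data.frame(s)[, c("trait", "marker", "p_adj")]))
  traits <- colnames(pcorr$matrix)
  edges <- list()
  for (i in seq_along(traits)) for (j in seq_along(traits)) {
    if (i >= j) next
    if (!is.na(pcorr$p[i, j]) && pcorr$p[i, j] <= alpha)
      edges[[length(edges) + 1L]] <- data.frame(
        u = traits[i], v = traits[j], kind = "trait-trait",
        weight = abs(pcorr$matrix[i, j]))
  }
  sig <- sc[!is.na(sc$p_adj) & sc$p_adj <= alpha, , drop = FALSE]
  sig <- sig[sig$trait %in% traits, , drop = FALSE]
  sig <- sig[order(sig$marker, sig$trait), , drop = FALSE]
  if (nrow(sig)) {
    edges[[length(edges) + 1L]] <- data.frame(
      u = sig$marker, v = sig$trait, kind = "marker-trait",
      weight = -log10(pmax(sig$p_adj, .Machine$double.xmin)))
  }
  edges <- if (length(edges)) do.call(rbind, c(edges, list(make.row.names = FALSE)))
  else data.frame(u = character(0), v = character(0),
                  kind = character(0), weight = numeric(0))
  mk <- sort(unique(edges$u[edges$kind == "marker-trait"]))
  vertices <- rbind(data.frame(name = traits, role = "trait"),
                    if (length(mk)) data.frame(name = mk, role = "marker"))
  structure(list(vertices = vertices, edges = edges),
            class = "metabolite_network")
}

#' @export
print.metabolite_network <- function(x, ...) {
  cat("metabolite_network:", nrow(x$vertices), "vertices (",
      sum(x$vertices$role == "trait"), "traits,",
      sum(x$vertices$role == "marker"), "markers ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Pajek and edge-list export
#'
#' Pajek .net dialect: a \code{*Vertices n} section with 1-based ids and
#' quoted labels, then \code{*Edges} lines \code{u v weight}. The TSV
#' edge-list mirror carries the edge kind. \code{read_pajek} round-trips
#' topology and weights.
#'
#' @param net a \code{metabolite_network}.
#' @param path output path.
#' @export
write_pajek <- function(net, path) {
  v <- net$vertices
  if (any(!nzchar(v$name))) stop("vertex names must be non-empty")
  id <- seq_len(nrow(v))
  names(id) <- v$name
  lines <- c(sprintf("*Vertices %d", nrow(v)),
             sprintf('%d "%s"', id, v$name),
             "*Edges",
             if (nrow(net$edges))
               sprintf("%d %d %.10g", id[net$edges$u], id[net$edges$v],
                       net$edges$weight))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pajek
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("\\*Vertices\\s+", "", lines[1L], ignore.case = TRUE))
  vl <- lines[2:(1 + nv)]
  names_v <- sub('^\\s*\\d+\\s+"(.*)"\\s*$', "\\1", vl)
  eidx <- grep("^\\*Edges", lines, ignore.case = TRUE)[1L]
  el <- if (eidx < length(lines)) lines[(eidx + 1L):length(lines)] else character(0)
  el <- el[nzchar(trimws(el))]
  if (length(el)) {
    parts <- do.call(rbind, strsplit(trimws(el), "\\s+"))
    edges <- data.frame(u = names_v[as.integer(parts[, 1L])],
                        v = names_v[as.integer(parts[, 2L])],
                        kind = NA_character_,
                        weight = as.numeric(parts[, 3L]))
  } else {
    edges <- data.frame(u = character(0), v = character(0),
                        kind = character(0), weight = numeric(0))
  }
  structure(list(vertices = data.frame(name = names_v, role = NA_character_),
                 edges = edges), class = "metabolite_network")
}

#' @rdname write_pajek
#' @export
write_edgelist <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pajek
#' @export
write_vertex_table <- function(net, path) {
  utils::write.table(net$vertices, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
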