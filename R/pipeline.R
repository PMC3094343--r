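## Orchestration: simulate (or load) -> structure -> kinship -> four
## association scans -> random forest -> network -> method comparison, from a
## single config, with a manifest and a Table-1-style comparison grid.

# derive a stage seed from the global seed by stable hashing of the stage
# name, so adding a stage never shifts another stage's random stream
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' Exactly one of \code{sim} (a \code{\link{sim_config}}) or \code{paths}
#' (list with \code{markers} and \code{phenotypes} TSV paths) must be given.
#' Sub-configs hold the per-stage knobs; defaults are desk-scale (forest and
#' permutation counts well below the production defaults of
#' \code{\link{rf_config}}) so a full run stays interactive.
#'
#' @param sim optional \code{sim_config} for synthetic input.
#' @param paths optional list(markers=, phenotypes=) of input TSVs.
#' @param popstruct list: k, n_iter, burnin, threshold, use_true_q (synthetic
#'   runs may reuse the generator's Q instead of re-estimating).
#' @param kinship list: estimator ("freqcorr" or "jaccard").
#' @param assoc list: correction ("bh" or "maxt"), n_perm, alpha, min_freq.
#' @param rf list: n_trees, perm_trees, n_perm, alpha, mtry_grid.
#' @param network list: alpha, method ("inverse"/"shrinkage").
#' @param seed global seed; per-stage seeds are derived from it.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            popstruct = list(), kinship = list(),
                            assoc = list(), rf = list(), network = list(),
                            seed = 1L) {
  if (is.null(sim) == is.null(paths))
    stop("exactly one of 'sim' or 'paths' must be supplied")
  ps <- utils::modifyList(list(k = 4L, n_iter = 1500L, burnin = 500L,
                               threshold = 0.70, use_true_q = FALSE), popstruct)
  kn <- utils::modifyList(list(estimator = "freqcorr"), kinship)
  as_ <- utils::modifyList(list(correction = "bh", n_perm = 200L,
                                alpha = 0.05, min_freq = 0.10), assoc)
  rfc <- utils::modifyList(list(n_trees = 500L, perm_trees = 250L,
                                n_perm = 200L, alpha = 0.05,
                                mtry_grid = c(3L, 6L, 12L, 24L, 48L, 96L)), rf)
  nw <- utils::modifyList(list(alpha = 0.05, method = "inverse"), network)
  stopifnot(as_$alpha > 0, as_$alpha < 1, rfc$alpha > 0, rfc$alpha < 1,
            nw$alpha > 0, nw$alpha < 1)
  structure(list(sim = sim, paths = paths, popstruct = ps, kinship = kn,
                 assoc = as_, rf = rfc, network = nw,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.pipe_log <- function(stage, ...) message("[qkforest] ", stage, ": ", ...)

#' Run the full method-comparison pipeline
#'
#' Executes every stage in order, writes all artifacts plus a manifest of
#' md5 checksums under \code{out_dir}, and returns a comparison report.
#' Reruns with the same config and seed are bitwise identical. A stage
#' failure halts the pipeline with the failing stage named; artifacts of
#' completed stages remain on disk.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created).
#' @return class \code{comparison_report}: \code{counts} (method x trait
#'   significant-marker counts), \code{overlaps}, \code{sets},
#'   \code{marker_table}, \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    ## --- input -------------------------------------------------------------
    if (!is.null(config$sim)) {
      .pipe_log(stage, "simulating ", config$sim$n_accessions, " accessions")
      pop <- simulate_population(config$sim)
      markers <- simulate_markers(pop$Q, pop$subpop_allele_freqs,
                                  seed = .stage_seed(config$seed, "markers"))
      Ktruth <- kinship_freq_corrected(filter_markers(markers, 0.02))
      ph <- simulate_phenotypes(markers, pop$Q, Ktruth, config$sim)
      phenos <- ph$phenotypes
      write_sim_truth(ph$truth, config$sim, file.path(out_dir, "truth"))
      true_q <- pop$Q
    } else {
      .pipe_log(stage, "reading ", config$paths$markers)
      markers <- read_marker_matrix(config$paths$markers)
      phenos <- read_phenotype_table(config$paths$phenotypes)
      true_q <- NULL
    }
    write_marker_matrix(markers, file.path(out_dir, "markers.tsv"))
    write_phenotype_table(phenos, file.path(out_dir, "phenotypes.tsv"))

    ## --- marker preprocessing ---------------------------------------------
    stage <- "filter"
    struct_markers <- most_frequent_allele_subset(markers)
    assoc_markers <- filter_markers(markers, config$assoc$min_freq)
    .pipe_log(stage, ncol(assoc_markers$scores), " of ",
              ncol(markers$scores), " markers pass the frequency filter")

    ## --- population structure ---------------------------------------------
    stage <- "structure"
    if (isTRUE(config$popstruct$use_true_q) && !is.null(true_q)) {
      Q <- true_q
      .pipe_log(stage, "using generator ground-truth Q")
    } else {
      Q <- estimate_admixture(struct_markers, config$popstruct$k,
                              config$popstruct$n_iter, config$popstruct$burnin,
                              seed = .stage_seed(config$seed, "structure"))
    }
    write_admixture_q(Q, file.path(out_dir, "q_matrix.tsv"))
    labels <- assign_members(Q, config$popstruct$threshold)
    utils::write.table(data.frame(accession = names(labels), label = labels),
                       file.path(out_dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pc <- pco(jaccard_distance(struct_markers), n_axes = 2L)
    utils::write.table(data.frame(accession = rownames(pc$coordinates),
                                  pc$coordinates),
                       file.path(out_dir, "pco.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    ## --- kinship -----------------------------------------------------------
    stage <- "kinship"
    K <- if (config$kinship$estimator == "jaccard")
      kinship_jaccard(assoc_markers) else kinship_freq_corrected(assoc_markers)
    write_kinship(K, file.path(out_dir, "kinship.tsv"))

    ## --- association scans -------------------------------------------------
    stage <- "assoc"
    traits <- colnames(phenos$values)
    scans <- list()
    for (tr in traits) {
      yv <- phenos$values[, tr]
      sl <- list(`1` = scan_naive(assoc_markers, yv, trait = tr),
                 `2` = scan_q(assoc_markers, yv, Q, trait = tr),
                 `3` = scan_mixed(assoc_markers, yv, K, trait = tr),
                 `4` = scan_mixed(assoc_markers, yv, K, Q, trait = tr))
      for (mid in names(sl)) {
        s <- sl[[mid]]
        s$p_adj <- if (config$assoc$correction == "maxt") {
          adjust_resampling(assoc_markers, yv, as.integer(mid),
                            Q = Q, K = K, n_perm = config$assoc$n_perm,
                            seed = .stage_seed(config$seed,
                                               paste0("maxt", mid, tr)))
        } else adjust_fdr(s$p_raw)
        sl[[mid]] <- s
        write_assoc_scan(s, file.path(out_dir,
                                      sprintf("scan_model%s_%s.tsv", mid, tr)))
      }
      scans[[tr]] <- sl
    }

    ## --- random forest ------------------------------------------------------
    stage <- "rf"
    rf_scans <- list()
    for (tr in traits) {
      cfg_rf <- rf_config(n_trees = config$rf$n_trees,
                          mtry_grid = config$rf$mtry_grid,
                          n_perm = config$rf$n_perm, alpha = config$rf$alpha,
                          perm_trees = config$rf$perm_trees,
                          seed = .stage_seed(config$seed, paste0("rf", tr)))
      rf_scans[[tr]] <- rf_permutation_scan(assoc_markers,
                                            phenos$values[, tr], cfg_rf)
      write_rf_scan(rf_scans[[tr]],
                    file.path(out_dir, sprintf("rf_%s.tsv", tr)))
    }

    ## --- network ------------------------------------------------------------
    stage <- "network"
    if (length(traits) >= 2L) {
      pcor <- partial_correlation(phenos, method = config$network$method)
      m4 <- lapply(scans, `[[`, "4")
      net <- build_network(pcor, m4, alpha = config$network$alpha)
      write_pajek(net, file.path(out_dir, "network.net"))
      write_edgelist(net, file.path(out_dir, "network_edges.tsv"))
      write_vertex_table(net, file.path(out_dir, "network_vertices.tsv"))
    } else net <- NULL

    ## --- comparison ---------------------------------------------------------
    stage <- "compare"
    alpha <- config$assoc$alpha
    sets <- list()
    counts <- matrix(0L, 8L, length(traits),
                     dimnames = list(c("model1", "model2", "model3", "model4",
                                       "RF", "RF&model1", "RF&model3",
                                       "RF&model4"), traits))
    marker_rows <- list()
    for (tr in traits) {
      per <- list()
      for (mid in as.character(1:4)) {
        s <- scans[[tr]][[mid]]
        sig <- s$marker[!is.na(s$p_adj) & s$p_adj <= alpha]
        per[[paste0("model", mid)]] <- sig
        counts[paste0("model", mid), tr] <- length(sig)
        if (length(sig))
          marker_rows[[length(marker_rows) + 1L]] <-
            data.frame(trait = tr, method = paste0("model", mid), marker = sig)
      }
      rfsig <- rf_scans[[tr]]$marker[rf_scans[[tr]]$significant]
      per$RF <- rfsig
      counts["RF", tr] <- length(rfsig)
      for (mid in c("1", "3", "4"))
        counts[paste0("RF&model", mid), tr] <-
          length(intersect(rfsig, per[[paste0("model", mid)]]))
      if (length(rfsig))
        marker_rows[[length(marker_rows) + 1L]] <-
          data.frame(trait = tr, method = "RF", marker = rfsig)
      sets[[tr]] <- per
    }
    marker_table <- if (length(marker_rows))
      do.call(rbind, c(marker_rows, list(make.row.names = FALSE)))
    else data.frame(trait = character(0), method = character(0),
                    marker = character(0))
    report <- structure(list(counts = counts, sets = sets,
                             marker_table = marker_table, out_dir = out_dir),
                        class = "comparison_report")
    utils::write.table(report_table(report), file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(marker_table, file.path(out_dir, "significant_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- manifest -----------------------------------------------------------
    stage <- "manifest"
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.tsv"))
    md5 <- as.character(tools::md5sum(file.path(out_dir, files)))
    utils::write.table(data.frame(file = files, md5 = md5),
                       file.path(out_dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report
  }, error = function(e) {
    stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' Comparison grid in the style of a methods-comparison table
#'
#' Rows are the four linear models, RF, and the RF-by-model overlaps; columns
#' are traits; cells are counts of significant markers after multiple-testing
#' correction.
#'
#' @param report a \code{comparison_report}.
#' @return integer matrix.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  report$counts
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (", ncol(x$counts), "traits )\n")
  print(x$counts)
  invisible(x)
}
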