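## End-to-end orchestration: pedigree statistics, gene origin, inbreeding,
## genotype QC, ROH/F_roh/F_het, LD-based Ne, ancestry/network structure and
## ROH islands, with optional CSV/JSON outputs and a reproducibility
## manifest.

#' Run the full diversity analysis
#'
#' Executes every stage that its inputs allow: the pedigree stages always
#' run; the genomic stages run when `gd` is supplied. The estimator
#' correlation matrix (F_trad, F_rec, F_het, F_roh) is computed over
#' genotyped individuals present in the pedigree.
#'
#' @param ped a `herd_pedigree`.
#' @param gd a `geno_data`, or `NULL` for pedigree-only mode.
#' @param ref_years `c(from, to)` birth-year window of the reference
#'   population; default: the last ten years on record.
#' @param exclude_origin origins excluded from the reference population.
#' @param qc run marker QC before the genomic stages.
#' @param roh parameters from [roh_params()].
#' @param ld an [ld_config()].
#' @param k_values K values scanned by the ancestry stage.
#' @param n_runs NMF restarts per K.
#' @param struct_max_snps marker cap for the ancestry stage (evenly
#'   subsampled; admixture-style analyses do not need the full panel).
#' @param knn_k network neighbours.
#' @param island_thresholds sharing thresholds for ROH islands.
#' @param seed master seed for the stochastic stages.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param cor_method correlation for the estimator matrix.
#' @return list of class `herdvar_report`; main elements: `completeness`,
#'   `eqgen`, `generation_lengths`, `reference_ids`, `gene_origin`,
#'   `inbreeding`, `decades`, `qc_report`, `het`, `roh`, `roh_classes`,
#'   `froh`, `ne_trajectory`, `ancestry`, `assignment`, `network`,
#'   `subpop_diversity`, `islands`, `f_correlations`, `manifest`.
#' @export
run_all <- function(ped, gd = NULL, ref_years = NULL,
                    exclude_origin = "imported", qc = TRUE,
                    roh = roh_params(), ld = ld_config(alpha_mutation = 1),
                    k_values = 1:3, n_runs = 3L, struct_max_snps = 4000L,
                    knn_k = 10L,
                    island_thresholds = c(0.6, 0.7), seed = 1L,
                    out_dir = NULL, cor_method = "pearson") {
  t0 <- Sys.time()
  rep_out <- list()

  ## --- pedigree stages -------------------------------------------------
  rep_out$completeness <- pedigree_completeness(ped)
  eq <- equivalent_generations(ped)
  rep_out$eqgen <- eq
  rep_out$generation_lengths <- generation_lengths(ped)
  if (is.null(ref_years)) {
    last <- max(ped$birth_year, na.rm = TRUE)
    ref_years <- c(last - 9L, last)
  }
  ref_ids <- reference_population(ped, ref_years[1], ref_years[2],
                                  exclude_origin)
  rep_out$reference_ids <- ref_ids
  rep_out$gene_origin <- gene_origin(ped, ref_ids)
  inb <- inbreeding_table(ped)
  rep_out$inbreeding <- inb
  rep_out$decades <- decade_summary(ped, inb)

  ## --- genomic stages ---------------------------------------------------
  if (!is.null(gd)) {
    gd <- autosome_filter(gd)
    if (qc) {
      qcr <- qc_filter(gd)
      gd <- qcr$gd
      rep_out$qc_report <- qcr$report
    }
    rep_out$het <- het_inbreeding(gd)
    segments <- detect_roh(gd, roh)
    rep_out$roh <- segments
    rep_out$roh_classes <- roh_class_stats(segments)
    rep_out$froh <- froh(segments, rownames(gd$G), map_span_bp(gd$map))
    binned <- pairwise_r2_binned(gd, ld)
    rep_out$ne_trajectory <- ne_trajectory(binned, ld)

    gd_s <- gd
    if (ncol(gd$G) > struct_max_snps) {
      keep <- round(seq(1L, ncol(gd$G), length.out = struct_max_snps))
      gd_s <- geno_data(gd$G[, keep, drop = FALSE],
                        gd$map[keep, , drop = FALSE])
    }
    ce <- sapply(k_values, function(K)
      ancestry_nmf(gd_s, K, n_runs = n_runs, seed = seed)$cross_entropy)
    names(ce) <- k_values
    ks <- choose_k(ce)
    rep_out$k_table <- ks$table
    best <- ancestry_nmf(gd_s, ks$K, n_runs = n_runs, seed = seed + 17L)
    rep_out$ancestry <- best
    rep_out$assignment <- assign_subpops(best)
    D <- ibs_distance(gd)
    rep_out$network <- knn_network(D, k = min(knn_k, nrow(D) - 1L))
    if (ks$K >= 2L && all(rep_out$assignment$id %in% ped$id) &&
        length(unique(rep_out$assignment$subpop)) >= 2L) {
      rep_out$subpop_diversity <-
        subpop_diversity(ped, rep_out$assignment, rep_out$froh)
    }

    track <- roh_incidence(segments, gd$map, rownames(gd$G))
    rep_out$incidence <- track
    rep_out$islands <- lapply(stats::setNames(island_thresholds,
                                              paste0("t", island_thresholds)),
                              function(th) call_islands(track, th))

    ## estimator correlation matrix on shared individuals
    shared <- intersect(rownames(gd$G), ped$id)
    if (length(shared) >= 3L) {
      tab <- data.frame(
        F_trad = inb$F_trad[match(shared, inb$id)],
        F_rec = inb$F_rec[match(shared, inb$id)],
        F_het = rep_out$het$F_het[match(shared, rep_out$het$id)],
        F_roh = rep_out$froh$f_roh[match(shared, rep_out$froh$id)]
      )
      rep_out$f_correlations <- stats::cor(tab, method = cor_method)
      rep_out$f_table <- cbind(id = shared, tab)
    }
  }

  rep_out$manifest <- list(
    seed = seed, ref_years = ref_years, exclude_origin = exclude_origin,
    n_animals = nrow(ped),
    n_genotyped = if (is.null(gd)) 0L else nrow(gd$G),
    n_snps = if (is.null(gd)) 0L else ncol(gd$G),
    genomic_stages = !is.null(gd),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("herdvar"))
  )
  class(rep_out) <- "herdvar_report"

  if (!is.null(out_dir)) write_report(rep_out, out_dir)
  rep_out
}

#' Write the report bundle to disk
#'
#' @param report a `herdvar_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = ",",
                       quote = FALSE, row.names = FALSE)
  w(report$completeness$per_year, "completeness_by_year.csv")
  w(report$generation_lengths, "generation_lengths.csv")
  w(report$inbreeding, "inbreeding.csv")
  w(report$decades, "decades.csv")
  w(report$gene_origin$ancestors, "ancestor_contributions.csv")
  w(report$gene_origin$founders, "founder_contributions.csv")
  if (!is.null(report$roh)) w(as.data.frame(report$roh), "roh_segments.tsv")
  if (!is.null(report$roh_classes)) w(report$roh_classes, "roh_classes.csv")
  if (!is.null(report$froh)) w(report$froh, "froh.csv")
  if (!is.null(report$het)) w(report$het, "fhet.csv")
  if (!is.null(report$ne_trajectory)) w(report$ne_trajectory, "ne_trajectory.csv")
  if (!is.null(report$assignment)) w(report$assignment, "subpop_assignment.csv")
  if (!is.null(report$islands))
    for (nm in names(report$islands)) w(report$islands[[nm]],
                                        paste0("islands_", nm, ".csv"))
  if (!is.null(report$f_correlations))
    utils::write.table(report$f_correlations,
                       file.path(out_dir, "f_correlations.csv"),
                       sep = ",", quote = FALSE, col.names = NA)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.herdvar_report <- function(x, ...) {
  cat("herdvar_report\n")
  cat("  animals:", x$manifest$n_animals,
      "| genotyped:", x$manifest$n_genotyped,
      "| SNPs:", x$manifest$n_snps, "\n")
  cat("  pedigree completeness:",
      sprintf("%.1f%%", 100 * x$completeness$overall_pc), "\n")
  s <- x$gene_origin$summary
  cat(sprintf("  f_e = %.1f, f_a = %.1f, fa/fe = %.2f, a50 = %d\n",
              s$f_e, s$f_a, s$ratio_fa_fe, s$a50))
  tot <- x$decades[x$decades$decade == "Total", ]
  cat(sprintf("  mean F_trad = %.2f%%, F_rec = %.2f%%, Ne_ped = %.1f\n",
              tot$F_trad_pct, tot$F_rec_pct, tot$Ne_ped))
  if (!is.null(x$froh))
    cat(sprintf("  mean F_roh = %.2f%%, mean F_het = %.2f%%, %d ROH\n",
                100 * mean(x$froh$f_roh), 100 * mean(x$het$F_het, na.rm = TRUE),
                nrow(x$roh)))
  invisible(x)
}
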