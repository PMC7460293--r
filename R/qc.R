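## Marker quality control: MAF, call rate, Hardy-Weinberg exact test,
## autosome restriction.

#' Exact Hardy--Weinberg test on genotype counts
#'
#' Two-sided exact test (sum of probabilities of heterozygote counts no more
#' likely than the observed one, conditional on the allele counts), computed
#' with the stable ratio recurrence. Mid-p correction off.
#'
#' @param n_het,n_hom1,n_hom2 genotype counts (hom1 = homozygous for the
#'   rarer allele).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  ## possible het counts share the parity of n_rare
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  lp <- numeric(length(hets))
  ## log-probabilities via the ratio recurrence upward from the smallest
  ## heterozygote count: P(h)/P(h-2) = 4 (hom_r+1)(hom_c+1) / (h (h-1))
  if (length(hets) > 1L) {
    for (k in 2:length(hets)) {
      h <- hets[k]
      hom_r <- (n_rare - h) / 2          # rare homozygotes at h hets
      lp[k] <- lp[k - 1] + log(4) + log(hom_r + 1) +
        log(n - (n_rare + h) / 2 + 1) - log(h) - log(h - 1)
    }
  }
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

#' Restrict genotypes to autosomal markers
#'
#' @param gd a `geno_data`.
#' @param autosome_labels chromosome labels to keep (default `as.character(1:31)`,
#'   the horse autosomes).
#' @return filtered `geno_data`.
#' @export
autosome_filter <- function(gd, autosome_labels = as.character(1:31)) {
  keep <- gd$map$chr %in% autosome_labels
  gd2 <- geno_data(gd$G[, keep, drop = FALSE],
                   gd$map[keep, , drop = FALSE])
  gd2$map <- droplevels_df(gd2$map)
  gd2
}

droplevels_df <- function(df) { rownames(df) <- NULL; df }

#' Marker quality control
#'
#' Applies, in order: minor-allele-frequency filter (drop MAF < `maf_min`),
#' call-rate filter (drop call rate <= `callrate_min_exclusive`, i.e. the
#' boundary itself is dropped), and an exact Hardy--Weinberg test (drop
#' p < `hwe_p_min`). MAF is computed on non-missing genotypes.
#'
#' @param gd a `geno_data` (typically after [autosome_filter()]).
#' @param maf_min MAF threshold (inclusive keep: MAF >= maf_min).
#' @param callrate_min_exclusive call-rate boundary; loci at or below are dropped.
#' @param hwe_p_min HWE p-value threshold.
#' @return list `gd` (filtered), `report` (class `qc_report`).
#' @export
qc_filter <- function(gd, maf_min = 0.01, callrate_min_exclusive = 0.90,
                      hwe_p_min = 1e-6) {
  G <- gd$G
  if (ncol(G) == 0L) stop("no loci to filter")
  n_input <- ncol(G)
  nm <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * nm)
  p[nm == 0] <- 0
  maf <- pmin(p, 1 - p)
  drop_maf <- maf < maf_min
  snp_ids <- gd$map$snp_id

  keep1 <- !drop_maf
  callrate <- nm / nrow(G)
  drop_cr <- keep1 & callrate <= callrate_min_exclusive
  keep2 <- keep1 & !drop_cr

  drop_hwe <- rep(FALSE, ncol(G))
  for (j in which(keep2)) {
    g <- G[, j]
    n_het <- sum(g == 1L, na.rm = TRUE)
    n_alt <- sum(g == 2L, na.rm = TRUE)   # hom for counted (minor) allele
    n_ref <- sum(g == 0L, na.rm = TRUE)
    if (hwe_exact_test(n_het, min(n_alt, n_ref), max(n_alt, n_ref)) < hwe_p_min)
      drop_hwe[j] <- TRUE
  }
  keep3 <- keep2 & !drop_hwe

  if (!any(keep3)) stop("quality control removed every locus")
  report <- structure(list(
    n_input = n_input,
    n_after_maf = sum(keep1),
    n_after_callrate = sum(keep2),
    n_after_hwe = sum(keep3),
    dropped_maf = snp_ids[drop_maf],
    dropped_callrate = snp_ids[drop_cr],
    dropped_hwe = snp_ids[drop_hwe],
    params = list(maf_min = maf_min,
                  callrate_min_exclusive = callrate_min_exclusive,
                  hwe_p_min = hwe_p_min),
    filter_order = c("maf", "callrate", "hwe")
  ), class = "qc_report")
  list(gd = geno_data(G[, keep3, drop = FALSE],
                      droplevels_df(gd$map[keep3, , drop = FALSE])),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$n_input, "loci in;",
      "MAF ->", x$n_after_maf, "; call rate ->", x$n_after_callrate,
      "; HWE ->", x$n_after_hwe, "retained\n")
  invisible(x)
}
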