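## Historical effective population size from binned linkage-disequilibrium
## decay, in the spirit of the Sved (1971) expectation
## E[r^2] = 1/(alpha + 4 N_e c): each inter-SNP distance bin maps to a
## recombination fraction c and to a time horizon t = 1/(2c) generations ago.

#' LD / Ne estimation configuration
#'
#' @param min_dist_mb,max_dist_mb inter-SNP distance window (Mb).
#' @param cm_per_mb genome-wide average recombination rate.
#' @param alpha_mutation Sved--Feldman mutation modifier: 1 (none) or 2.2.
#' @param sample_correction `"unphased"` (subtract 1/n), `"phased"`
#'   (subtract 1/(2n)) or `"none"`.
#' @param n_bins number of log-spaced distance bins.
#' @return list of class `ld_config`.
#' @export
ld_config <- function(min_dist_mb = 0.5, max_dist_mb = 26, cm_per_mb = 1.24,
                      alpha_mutation = 2.2,
                      sample_correction = c("unphased", "phased", "none"),
                      n_bins = 18L) {
  stopifnot(min_dist_mb > 0, max_dist_mb > min_dist_mb, cm_per_mb > 0)
  structure(list(min_dist_mb = min_dist_mb, max_dist_mb = max_dist_mb,
                 cm_per_mb = cm_per_mb, alpha_mutation = alpha_mutation,
                 sample_correction = match.arg(sample_correction),
                 n_bins = as.integer(n_bins)),
            class = "ld_config")
}

## Haldane map function: physical distance (Mb) -> recombination fraction
haldane_c <- function(dist_mb, cm_per_mb) {
  morgans <- dist_mb * cm_per_mb / 100
  0.5 * (1 - exp(-2 * morgans))
}

#' Binned pairwise r-squared by inter-SNP distance
#'
#' Computes the squared genotypic (composite) correlation between dosage
#' vectors for every intra-chromosome SNP pair with separation inside the
#' configured window, and averages within log-spaced distance bins.
#'
#' @param gd a `geno_data` (QC'd autosomal markers).
#' @param cfg an [ld_config()].
#' @return data.frame `bin`, `mean_dist_mb`, `mean_r2`, `n_pairs`, with
#'   attribute `n_ind` (sample size); empty bins are dropped with a warning.
#' @export
pairwise_r2_binned <- function(gd, cfg = ld_config()) {
  brks <- exp(seq(log(cfg$min_dist_mb), log(cfg$max_dist_mb),
                  length.out = cfg$n_bins + 1L))
  sums_r2 <- numeric(cfg$n_bins)
  sums_d <- numeric(cfg$n_bins)
  counts <- integer(cfg$n_bins)
  for (ch in unique(gd$map$chr)) {
    sel <- which(gd$map$chr == ch)
    if (length(sel) < 2L) next
    sel <- sel[order(gd$map$bp[sel])]
    pos <- gd$map$bp[sel] / 1e6
    X <- gd$G[, sel, drop = FALSE]
    sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
    ok <- !is.na(sdv) & sdv > 0
    R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
    R[!ok, ] <- NA; R[, !ok] <- NA
    D <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(D)
    d <- D[ut]; r2 <- R[ut]^2
    keep <- d >= cfg$min_dist_mb & d <= cfg$max_dist_mb & !is.na(r2)
    if (!any(keep)) next
    b <- findInterval(d[keep], brks, rightmost.closed = TRUE)
    b[b > cfg$n_bins] <- cfg$n_bins
    sums_r2 <- sums_r2 + as.numeric(tapply(r2[keep], factor(b, 1:cfg$n_bins),
                                           sum, default = 0))
    sums_d <- sums_d + as.numeric(tapply(d[keep], factor(b, 1:cfg$n_bins),
                                         sum, default = 0))
    counts <- counts + as.integer(table(factor(b, 1:cfg$n_bins)))
  }
  empty <- counts == 0L
  if (any(empty)) warning(sum(empty), " empty distance bin(s) dropped")
  out <- data.frame(bin = which(!empty),
                    mean_dist_mb = sums_d[!empty] / counts[!empty],
                    mean_r2 = sums_r2[!empty] / counts[!empty],
                    n_pairs = counts[!empty])
  attr(out, "n_ind") <- nrow(gd$G)
  out
}

#' Historical Ne trajectory from binned r-squared
#'
#' Per bin: recombination fraction c from the mean distance via the Haldane
#' map at `cm_per_mb`; r-squared adjusted for finite sample size; then
#' \deqn{N_e = \frac{1}{4c}\left(\frac{1}{r^2_{adj}} - \alpha\right),\qquad
#'       t = \frac{1}{2c}.}
#' Bins yielding non-positive adjusted r-squared or Ne are dropped.
#'
#' @param binned output of [pairwise_r2_binned()].
#' @param cfg an [ld_config()].
#' @param n_ind sample size (defaults to the attribute on `binned`).
#' @return data.frame `generations_ago`, `ne`, `mean_dist_mb`, `mean_r2`,
#'   `n_pairs`, ordered by increasing distance; larger distances inform more
#'   recent generations (smaller `generations_ago`).
#' @export
ne_trajectory <- function(binned, cfg = ld_config(), n_ind = NULL) {
  if (is.null(n_ind)) n_ind <- attr(binned, "n_ind")
  corr <- switch(cfg$sample_correction,
                 unphased = 1 / n_ind,
                 phased = 1 / (2 * n_ind),
                 none = 0)
  c_bin <- haldane_c(binned$mean_dist_mb, cfg$cm_per_mb)
  r2_adj <- binned$mean_r2 - corr
  ne <- (1 / (4 * c_bin)) * (1 / r2_adj - cfg$alpha_mutation)
  t <- 1 / (2 * c_bin)
  ok <- is.finite(ne) & ne > 0 & r2_adj > 0
  if (!all(ok)) warning(sum(!ok), " bin(s) dropped (non-positive Ne)")
  out <- data.frame(generations_ago = t[ok], ne = ne[ok],
                    mean_dist_mb = binned$mean_dist_mb[ok],
                    mean_r2 = binned$mean_r2[ok],
                    n_pairs = binned$n_pairs[ok])
  out[order(out$mean_dist_mb), , drop = FALSE]
}

#' Expected r-squared under the Sved model
#'
#' Analytic forward model used for round-trip checks:
#' \eqn{E[r^2] = 1/(\alpha + 4 N_e c)}.
#'
#' @param c_vec recombination fractions.
#' @param ne effective population size.
#' @param alpha mutation modifier.
#' @return numeric vector.
#' @export
sved_expected_r2 <- function(c_vec, ne, alpha = 1) {
  1 / (alpha + 4 * ne * c_vec)
}

#' Physical distance giving a target recombination fraction
#'
#' Inverse of the Haldane mapping used by [ne_trajectory()].
#'
#' @param c_target recombination fraction(s) < 0.5.
#' @param cm_per_mb recombination rate.
#' @return distance in Mb.
#' @export
dist_for_c <- function(c_target, cm_per_mb = 1.24) {
  morgans <- -log(1 - 2 * c_target) / 2
  morgans * 100 / cm_per_mb
}
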