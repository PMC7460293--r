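## Genomic inbreeding: excess-homozygosity F_het, runs of homozygosity
## detected with the consecutive-runs method, F_roh, and length-class tables.

#' Excess-homozygosity inbreeding (method-of-moments)
#'
#' Per individual over its non-missing loci, compares the observed count of
#' homozygous genotypes with the expectation under Hardy--Weinberg using the
#' small-sample-corrected heterozygosity \eqn{2\hat p(1-\hat p)\,2n/(2n-1)}:
#' \deqn{F = (O_{hom} - E_{hom}) / (N - E_{hom}).}
#'
#' @param gd a `geno_data` (QC'd autosomal markers).
#' @return data.frame `id`, `o_hom`, `e_hom`, `n_nonmissing`, `F_het`.
#' @export
het_inbreeding <- function(gd) {
  G <- gd$G
  nm <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * nm)
  p[nm == 0] <- 0
  corr <- ifelse(nm > 0, 2 * nm / (2 * nm - 1), 1)
  e_hom_locus <- 1 - 2 * p * (1 - p) * corr
  obs <- !is.na(G)
  O <- rowSums(G == 0L | G == 2L, na.rm = TRUE)
  N <- rowSums(obs)
  E <- as.numeric(obs %*% e_hom_locus)
  Fh <- ifelse(N > 0 & (N - E) != 0, (O - E) / (N - E), NA_real_)
  data.frame(id = rownames(G), o_hom = O, e_hom = E, n_nonmissing = N,
             F_het = Fh, row.names = NULL, stringsAsFactors = FALSE)
}

#' ROH detection parameters
#'
#' Defaults follow the common consecutive-runs criteria for medium-density
#' equine panels: at least 15 SNPs and 500 kb per run, successive-SNP gaps at
#' most 1000 kb, density at least 1 SNP per 100 kb, and at most one
#' heterozygous and one missing call per run.
#'
#' @param min_snps minimum SNPs in a run.
#' @param min_length_bp minimum run length (end - start).
#' @param max_gap_bp maximum gap between successive SNPs in a run.
#' @param density_bp_per_snp maximum bp per SNP (density floor).
#' @param max_het,max_missing per-run allowances.
#' @return list of parameters.
#' @export
roh_params <- function(min_snps = 15L, min_length_bp = 5e5, max_gap_bp = 1e6,
                       density_bp_per_snp = 1e5, max_het = 1L,
                       max_missing = 1L) {
  list(min_snps = min_snps, min_length_bp = min_length_bp,
       max_gap_bp = max_gap_bp, density_bp_per_snp = density_bp_per_snp,
       max_het = max_het, max_missing = max_missing)
}

## maximal qualifying runs for one dosage vector on one chromosome;
## returns matrix of row indices (l, r) into pos
scan_runs <- function(g, pos, par) {
  L <- length(g)
  if (L == 0L) return(cbind(l = integer(0), r = integer(0)))
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  gap_ok <- if (L > 1L) diff(pos) <= par$max_gap_bp else logical(0)

  qualifies <- function(l, r) {
    n <- r - l + 1L
    len <- pos[r] - pos[l]
    n >= par$min_snps && len >= par$min_length_bp &&
      n * par$density_bp_per_snp >= len
  }

  cand_l <- integer(0); cand_r <- integer(0)
  r <- 0L; nh <- 0L; nm <- 0L
  for (l in seq_len(L)) {
    if (r < l) { r <- l; nh <- as.integer(het[l]); nm <- as.integer(mis[l]) }
    if (hom[l]) {
    ## extend right frontier under gap and per-run allowance constraints
    repeat {
      if (r == L) break
      if (!gap_ok[r]) break
      nh2 <- nh + het[r + 1L]; nm2 <- nm + mis[r + 1L]
      if (nh2 > par$max_het || nm2 > par$max_missing) break
      r <- r + 1L; nh <- nh2; nm <- nm2
    }
    ## largest qualifying end for this start (must end on a homozygote);
    ## shrinking the run only shortens it, so stop below the length floor
    rr <- r
    while (rr > l) {
      if (pos[rr] - pos[l] < par$min_length_bp) break
      if (hom[rr] && qualifies(l, rr)) {
        cand_l <- c(cand_l, l); cand_r <- c(cand_r, rr); break
      }
      rr <- rr - 1L
    }
    }
    ## shift window: drop l before moving on
    nh <- nh - het[l]; nm <- nm - mis[l]
  }
  if (!length(cand_l)) return(cbind(l = integer(0), r = integer(0)))
  ## containment-maximal: increasing l, keep candidates extending the frontier
  keep <- logical(length(cand_l))
  rmax <- -1L
  for (k in seq_along(cand_l)) {
    if (cand_r[k] > rmax) { keep[k] <- TRUE; rmax <- cand_r[k] }
  }
  cbind(l = cand_l[keep], r = cand_r[keep])
}

#' Detect runs of homozygosity (consecutive-runs method)
#'
#' Scans each individual and chromosome for maximal runs of homozygous
#' genotypes satisfying all criteria in [roh_params()]: runs never start or
#' end on a heterozygous or missing call, allowances are per-run totals, and
#' run length is `end_bp - start_bp`. Emitted runs are maximal: no emitted
#' run is contained in another qualifying run.
#'
#' @param gd a `geno_data`.
#' @param params see [roh_params()].
#' @return data.frame of class `roh_segments`: `id`, `chr`, `start_bp`,
#'   `end_bp`, `n_snps`, `n_het`, `n_missing`, `length_bp`.
#' @export
detect_roh <- function(gd, params = roh_params()) {
  map <- gd$map
  out <- list()
  for (ch in unique(map$chr)) {
    sel <- which(map$chr == ch)
    sel <- sel[order(map$bp[sel])]
    pos <- map$bp[sel]
    for (i in seq_len(nrow(gd$G))) {
      g <- gd$G[i, sel]
      runs <- scan_runs(g, pos, params)
      if (nrow(runs)) {
        het <- !is.na(g) & g == 1L
        mis <- is.na(g)
        out[[length(out) + 1L]] <- data.frame(
          id = rownames(gd$G)[i], chr = ch,
          start_bp = pos[runs[, "l"]], end_bp = pos[runs[, "r"]],
          n_snps = runs[, "r"] - runs[, "l"] + 1L,
          n_het = vapply(seq_len(nrow(runs)), function(k)
            sum(het[runs[k, "l"]:runs[k, "r"]]), integer(1)),
          n_missing = vapply(seq_len(nrow(runs)), function(k)
            sum(mis[runs[k, "l"]:runs[k, "r"]]), integer(1)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(0), chr = character(0),
               start_bp = integer(0), end_bp = integer(0),
               n_snps = integer(0), n_het = integer(0),
               n_missing = integer(0), stringsAsFactors = FALSE)
  res$length_bp <- res$end_bp - res$start_bp
  rownames(res) <- NULL
  class(res) <- c("roh_segments", "data.frame")
  res
}

#' Autosomal span covered by a marker map
#'
#' First-to-last SNP per chromosome, summed; the default denominator of
#' [froh()].
#'
#' @param map a marker map data.frame (`chr`, `bp`).
#' @return span in bp.
#' @export
map_span_bp <- function(map) {
  sum(vapply(split(map$bp, map$chr), function(b) max(b) - min(b), numeric(1)))
}

#' Genomic inbreeding from runs of homozygosity
#'
#' \eqn{F_{ROH} = \sum L_{ROH} / L_{AUTO}} per individual; individuals
#' without any run get 0.
#'
#' @param segments a `roh_segments` data.frame.
#' @param ids all genotyped individual ids (so ROH-free individuals appear).
#' @param L_auto_bp autosomal denominator in bp (e.g. [map_span_bp()]).
#' @return data.frame `id`, `sum_roh_bp`, `f_roh`.
#' @export
froh <- function(segments, ids, L_auto_bp) {
  if (L_auto_bp <= 0) stop("L_auto_bp must be positive")
  tot <- tapply(segments$length_bp, segments$id, sum)
  s <- as.numeric(tot[ids])
  s[is.na(s)] <- 0
  data.frame(id = ids, sum_roh_bp = s, f_roh = s / L_auto_bp,
             stringsAsFactors = FALSE)
}

#' ROH length-class summary table
#'
#' Classifies runs into left-open/right-closed Mb bins and reports, per
#' class: individuals with at least one run, run count and its share of the
#' total, mean run count per individual carrying runs of the class, and mean
#' run length in Mb.
#'
#' @param segments a `roh_segments` data.frame.
#' @param boundaries_mb inner class boundaries in Mb.
#' @return data.frame `class`, `n_individuals`, `n_roh`, `pct_n_roh`,
#'   `s_roh`, `l_roh_mb`.
#' @export
roh_class_stats <- function(segments, boundaries_mb = c(1, 2, 4, 8)) {
  brks <- c(0, boundaries_mb, Inf)
  labs <- c(paste0(c(0, boundaries_mb[-length(boundaries_mb)]), "-",
                   boundaries_mb),
            paste0(">", boundaries_mb[length(boundaries_mb)]))
  len_mb <- segments$length_bp / 1e6
  cls <- cut(len_mb, breaks = brks, labels = labs, right = TRUE)
  total <- nrow(segments)
  out <- lapply(seq_along(labs), function(k) {
    sel <- cls == labs[k]
    n <- sum(sel)
    data.frame(
      class = labs[k],
      n_individuals = length(unique(segments$id[sel])),
      n_roh = n,
      pct_n_roh = if (total > 0) n / total else NA_real_,
      s_roh = if (n > 0) n / length(unique(segments$id[sel])) else NA_real_,
      l_roh_mb = if (n > 0) mean(len_mb[sel]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
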