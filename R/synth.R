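## Synthetic data with known truth: a multi-decade studbook-like pedigree
## with episodic entry of unrelated imported founders and two sub-lineages
## created by differential sire use, plus genotypes generated by dropping
## labelled founder haplotypes through the pedigree on a linkage map. True
## autozygosity (fraction of the genome identical by descent) is tracked
## exactly from the haplotype labels.

#' Simulation configuration
#'
#' Defaults emulate a heavy-horse studbook at desk scale: ten decades of
#' records, a closed native base enlarged by two import episodes whose
#' stallions are used mostly by one lineage, few breeding sires per decade
#' (strong drift), and a 16 x 50 Mb genome (about a third of the equine
#' autosomal span) at one SNP per 50 kb, so that per-individual ROH-based
#' statistics have stable ranks.
#'
#' @param n_decades number of decades simulated.
#' @param start_year first birth year.
#' @param n_founders base founders in decade 1.
#' @param imports_per_decade integer vector (length `n_decades`): unrelated
#'   imported founders entering each decade.
#' @param offspring_per_decade newborns per decade (from decade 2 on).
#' @param sires_per_lineage breeding sires sampled per lineage per decade.
#' @param import_use_l1 probability that an imported new sire is assigned to
#'   lineage L1 (differential import use creates the two sub-lineages).
#' @param cross_lineage_mating probability a dam is mated to a sire of the
#'   other lineage.
#' @param n_chromosomes,chrom_length_mb,snp_spacing_kb,cm_per_mb genome and
#'   marker-grid parameters for [gene_drop()].
#' @param founder_maf_range founder allele frequencies are Beta(0.5, 0.5)
#'   truncated to this range.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_decades = 10L, start_year = 1930L, n_founders = 40L,
                       imports_per_decade = NULL, offspring_per_decade = 80L,
                       sires_per_lineage = 6L, import_use_l1 = 0.8,
                       cross_lineage_mating = 0.1,
                       n_chromosomes = 16L, chrom_length_mb = 50,
                       snp_spacing_kb = 50, cm_per_mb = 1.24,
                       founder_maf_range = c(0.05, 0.95)) {
  if (is.null(imports_per_decade)) {
    imports_per_decade <- integer(n_decades)
    if (n_decades >= 4L) imports_per_decade[4L] <- 12L
    if (n_decades >= 6L) imports_per_decade[6L] <- 12L
  }
  stopifnot(length(imports_per_decade) == n_decades, n_founders >= 4L)
  structure(list(
    n_decades = as.integer(n_decades), start_year = as.integer(start_year),
    n_founders = as.integer(n_founders),
    imports_per_decade = as.integer(imports_per_decade),
    offspring_per_decade = as.integer(offspring_per_decade),
    sires_per_lineage = as.integer(sires_per_lineage),
    import_use_l1 = import_use_l1,
    cross_lineage_mating = cross_lineage_mating,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_mb = chrom_length_mb, snp_spacing_kb = snp_spacing_kb,
    cm_per_mb = cm_per_mb, founder_maf_range = founder_maf_range
  ), class = "sim_config")
}

#' Simulate a two-lineage studbook pedigree
#'
#' Decade 1 creates the native founder base (split into lineages L1/L2);
#' later decades add imported founders per schedule and breed
#' `offspring_per_decade` newborns. Dams come from the two previous decades
#' of their lineage; each decade uses only `sires_per_lineage` sires per
#' lineage, with imported stallions entering the L1 pool with probability
#' `import_use_l1`. Offspring inherit the dam's lineage.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list `ped` (a `herd_pedigree`), `lineage` (data.frame `id`,
#'   `lineage`).
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  id <- character(0); sire <- character(0); dam <- character(0)
  year <- integer(0); sex <- character(0); origin <- character(0)
  lineage <- character(0)
  counter <- 0L
  new_id <- function() { counter <<- counter + 1L; sprintf("A%05d", counter) }

  add <- function(s, d, y, sx, org, lin) {
    i <- new_id()
    id <<- c(id, i); sire <<- c(sire, s); dam <<- c(dam, d)
    year <<- c(year, y); sex <<- c(sex, sx); origin <<- c(origin, org)
    lineage <<- c(lineage, lin)
    i
  }

  dec_start <- function(d) cfg$start_year + 10L * (d - 1L)

  ## decade 1: native base, half of each sex, lineages alternating
  for (k in seq_len(cfg$n_founders)) {
    add(NA, NA, dec_start(1L) + sample(0:9, 1L),
        if (k %% 2L) "M" else "F", "native",
        if (k <= cfg$n_founders / 2) "L1" else "L2")
  }

  for (d in 2:cfg$n_decades) {
    y0 <- dec_start(d)
    ## imported founders enter at the start of the decade
    n_imp <- cfg$imports_per_decade[d]
    if (n_imp > 0L) {
      for (k in seq_len(n_imp)) {
        lin <- if (stats::runif(1) < cfg$import_use_l1) "L1" else "L2"
        add(NA, NA, y0 - 10L + sample(0:9, 1L),
            if (k %% 2L) "M" else "F", "imported", lin)
      }
    }
    ## candidate parents: snapshot of animals born in the two previous decades
    prev_idx <- which(year >= y0 - 20L & year < y0)
    pool_by <- function(sx, lin)
      id[prev_idx[sex[prev_idx] == sx & lineage[prev_idx] == lin]]
    all_dams <- id[prev_idx[sex[prev_idx] == "F"]]
    sire_pool <- list()
    dam_pool <- list()
    for (lin in c("L1", "L2")) {
      males <- pool_by("M", lin)
      if (!length(males)) stop("lineage ", lin, " has no available sires in ",
                               "decade ", d, "; enlarge the cohorts")
      sire_pool[[lin]] <-
        sample(males, min(cfg$sires_per_lineage, length(males)))
      dam_pool[[lin]] <- pool_by("F", lin)
    }
    for (k in seq_len(cfg$offspring_per_decade)) {
      lin <- if (k %% 2L) "L1" else "L2"
      dams <- dam_pool[[lin]]
      if (!length(dams)) dams <- all_dams
      if (!length(dams)) stop("no available dams in decade ", d)
      dm <- sample(dams, 1L)
      slin <- if (stats::runif(1) < cfg$cross_lineage_mating)
        setdiff(c("L1", "L2"), lin) else lin
      sr <- sample(sire_pool[[slin]], 1L)
      add(sr, dm, y0 + sample(0:9, 1L),
          if (stats::runif(1) < 0.5) "M" else "F", "native", lin)
    }
  }
  ped <- pedigree(id, sire, dam, year, sex, origin)
  truth <- data.frame(id = id, lineage = lineage, stringsAsFactors = FALSE)
  list(ped = ped, lineage = truth[match(ped$id, truth$id), , drop = FALSE])
}

#' Simulate a constant-size random-mating pedigree
#'
#' Discrete generations, equal sex ratio, parents drawn uniformly from the
#' previous generation; birth year = generation index. Useful for checking
#' estimators against a known effective population size of about `n_per_gen`.
#'
#' @param n_per_gen individuals per generation.
#' @param n_generations number of bred generations after the founders.
#' @param seed integer seed.
#' @return a `herd_pedigree`.
#' @export
simulate_random_mating_pedigree <- function(n_per_gen = 50L,
                                            n_generations = 30L, seed = 1L) {
  set.seed(seed)
  id <- sprintf("G00I%03d", seq_len(n_per_gen))
  sex <- rep(c("M", "F"), length.out = n_per_gen)
  all_id <- id; all_sire <- rep(NA_character_, n_per_gen)
  all_dam <- rep(NA_character_, n_per_gen)
  all_year <- rep(0L, n_per_gen); all_sex <- sex
  prev_m <- id[sex == "M"]; prev_f <- id[sex == "F"]
  for (g in seq_len(n_generations)) {
    nid <- sprintf("G%02dI%03d", g, seq_len(n_per_gen))
    nsex <- rep(c("M", "F"), length.out = n_per_gen)
    all_id <- c(all_id, nid)
    all_sire <- c(all_sire, sample(prev_m, n_per_gen, replace = TRUE))
    all_dam <- c(all_dam, sample(prev_f, n_per_gen, replace = TRUE))
    all_year <- c(all_year, rep(g, n_per_gen))
    all_sex <- c(all_sex, nsex)
    prev_m <- nid[nsex == "M"]; prev_f <- nid[nsex == "F"]
  }
  pedigree(all_id, all_sire, all_dam, all_year, all_sex)
}

## ---- gene dropping ----------------------------------------------------

## haplotype = list(end = numeric ends (bp, tiles (0, len]), lab = integer)
new_hap <- function(len_bp, label) list(end = len_bp, lab = label)

## recombine two parental haplotypes: Poisson(morgans) crossovers, Haldane
meiosis_hap <- function(hapA, hapB, len_bp, morgans) {
  nx <- stats::rpois(1L, morgans)
  cur <- stats::runif(1) < 0.5
  if (nx == 0L) return(if (cur) hapA else hapB)
  xp <- sort(stats::runif(nx, 0, len_bp))
  bounds <- c(0, xp, len_bp)
  ends <- numeric(0); labs <- integer(0)
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    if (hi <= lo) { cur <- !cur; next }
    h <- if (cur) hapA else hapB
    i1 <- findInterval(lo, h$end, left.open = FALSE) + 1L
    i2 <- findInterval(hi, h$end, left.open = TRUE) + 1L
    i2 <- min(i2, length(h$end))
    seg_end <- pmin(h$end[i1:i2], hi)
    seg_lab <- h$lab[i1:i2]
    ends <- c(ends, seg_end); labs <- c(labs, seg_lab)
    cur <- !cur
  }
  ## merge adjacent segments with identical labels
  if (length(labs) > 1L) {
    keep <- c(labs[-length(labs)] != labs[-1L], TRUE)
    ends <- ends[keep]; labs <- labs[keep]
  }
  list(end = ends, lab = labs)
}

## shared (autozygous) length between two haplotypes of one chromosome
autozygous_length <- function(h1, h2) {
  b <- sort(unique(c(h1$end, h2$end)))
  starts <- c(0, b[-length(b)])
  mids <- (starts + b) / 2
  l1 <- h1$lab[findInterval(mids, h1$end) + 1L]
  l2 <- h2$lab[findInterval(mids, h2$end) + 1L]
  sum((b - starts)[l1 == l2])
}

## label at given positions
hap_labels_at <- function(h, pos) h$lab[findInterval(pos, h$end, left.open = TRUE) + 1L]

#' Drop founder haplotypes through a pedigree
#'
#' Founders (and every unknown-parent slot) receive uniquely labelled
#' haplotypes; each meiosis recombines the parental pair with Poisson
#' crossovers on the Haldane map. Genotypes are emitted on a regular marker
#' grid from founder-specific alleles drawn from truncated Beta(0.5, 0.5)
#' frequencies; true autozygosity is the genome fraction where the two
#' haplotype labels coincide.
#'
#' @param ped a `herd_pedigree`.
#' @param cfg a [sim_config()] (genome fields are used).
#' @param seed integer seed.
#' @param genotype_ids ids to emit genotypes for (default: all animals).
#' @return list `gd` (a `geno_data` for `genotype_ids`), `truth`
#'   (data.frame `id`, `true_autozygosity` for all animals), `n_founder_haps`.
#' @export
gene_drop <- function(ped, cfg = sim_config(), seed = 1L,
                      genotype_ids = ped$id) {
  set.seed(seed)
  n <- nrow(ped)
  n_chr <- cfg$n_chromosomes
  len_bp <- cfg$chrom_length_mb * 1e6
  morgans <- cfg$chrom_length_mb * cfg$cm_per_mb / 100
  spacing <- cfg$snp_spacing_kb * 1e3
  marker_pos <- seq(spacing / 2, len_bp, by = spacing)
  L_chr <- length(marker_pos)

  ## founder allele frequencies per chromosome/marker
  rtbeta <- function(m, lo, hi) {
    x <- stats::rbeta(m, 0.5, 0.5)
    pmin(pmax(x, lo), hi)
  }
  freqs <- lapply(seq_len(n_chr), function(ch)
    rtbeta(L_chr, cfg$founder_maf_range[1], cfg$founder_maf_range[2]))

  ## founder haplotype alleles, grown as labels are created
  hap_alleles <- lapply(seq_len(n_chr), function(ch)
    matrix(integer(0), nrow = 0, ncol = L_chr))
  n_labels <- 0L
  new_founder_hap <- function() {
    n_labels <<- n_labels + 1L
    for (ch in seq_len(n_chr)) {
      hap_alleles[[ch]] <<- rbind(hap_alleles[[ch]],
                                  stats::rbinom(L_chr, 1L, freqs[[ch]]))
    }
    n_labels
  }

  ## haps[[i]][[ch]] = list(h1, h2)
  haps <- vector("list", n)
  founder_gamete <- function() {
    lab <- integer(n_chr * 0)
    hs <- vector("list", n_chr)
    l1 <- new_founder_hap()
    for (ch in seq_len(n_chr)) hs[[ch]] <- new_hap(len_bp, l1)
    hs
  }
  gamete_from <- function(idx) {
    hs <- vector("list", n_chr)
    for (ch in seq_len(n_chr)) {
      pair <- haps[[idx]][[ch]]
      hs[[ch]] <- meiosis_hap(pair[[1L]], pair[[2L]], len_bp, morgans)
    }
    hs
  }
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    g1 <- if (s > 0L) gamete_from(s) else founder_gamete()
    g2 <- if (d > 0L) gamete_from(d) else founder_gamete()
    haps[[i]] <- lapply(seq_len(n_chr), function(ch) list(g1[[ch]], g2[[ch]]))
  }

  ## truth: genome fraction autozygous
  genome_len <- n_chr * len_bp
  ta <- vapply(seq_len(n), function(i)
    sum(vapply(seq_len(n_chr), function(ch)
      autozygous_length(haps[[i]][[ch]][[1L]], haps[[i]][[ch]][[2L]]),
      numeric(1))) / genome_len, numeric(1))
  truth <- data.frame(id = ped$id, true_autozygosity = ta,
                      stringsAsFactors = FALSE)

  ## genotypes on the marker grid
  gidx <- match(genotype_ids, ped$id)
  if (anyNA(gidx)) stop("genotype_ids not in pedigree")
  G <- matrix(NA_integer_, length(gidx), n_chr * L_chr)
  for (r in seq_along(gidx)) {
    i <- gidx[r]
    row <- integer(0)
    for (ch in seq_len(n_chr)) {
      pair <- haps[[i]][[ch]]
      lab1 <- hap_labels_at(pair[[1L]], marker_pos)
      lab2 <- hap_labels_at(pair[[2L]], marker_pos)
      a1 <- hap_alleles[[ch]][cbind(lab1, seq_len(L_chr))]
      a2 <- hap_alleles[[ch]][cbind(lab2, seq_len(L_chr))]
      row <- c(row, a1 + a2)
    }
    G[r, ] <- row
  }
  rownames(G) <- genotype_ids
  map <- data.frame(
    snp_id = sprintf("snp_%d_%d", rep(seq_len(n_chr), each = L_chr),
                     rep(seq_len(L_chr), n_chr)),
    chr = as.character(rep(seq_len(n_chr), each = L_chr)),
    bp = as.integer(rep(marker_pos, n_chr)),
    allele1 = "B", allele2 = "A", stringsAsFactors = FALSE
  )
  list(gd = geno_data(G, map), truth = truth, n_founder_haps = n_labels)
}

#' Plant a homozygous sweep haplotype in a region
#'
#' Overwrites the genotypes of a random fraction of individuals with a single
#' homozygous haplotype across the region (a designed ROH island).
#'
#' @param gd a `geno_data`.
#' @param chr chromosome label.
#' @param start_bp,end_bp region bounds.
#' @param carrier_fraction fraction of individuals receiving the haplotype.
#' @param seed integer seed.
#' @return modified `geno_data`.
#' @export
plant_sweep <- function(gd, chr, start_bp, end_bp, carrier_fraction,
                        seed = 1L) {
  set.seed(seed)
  sel <- which(gd$map$chr == chr & gd$map$bp >= start_bp &
                 gd$map$bp <= end_bp)
  if (!length(sel)) stop("region contains no markers (off map?)")
  if (carrier_fraction <= 0) return(gd)
  n <- nrow(gd$G)
  carriers <- sample(n, round(carrier_fraction * n))
  pattern <- 2L * stats::rbinom(length(sel), 1L, 0.5)
  for (i in carriers) gd$G[i, sel] <- pattern
  gd
}

#' Balding--Nichols two-population genotypes
#'
#' Independent SNPs; ancestral frequencies uniform on (0.1, 0.9) and
#' population frequencies Beta-drifted at the given Fst. Used to exercise the
#' ancestry and network estimators at a known divergence.
#'
#' @param n_per_pop individuals per population.
#' @param n_snps SNP count.
#' @param fst divergence parameter.
#' @param seed integer seed.
#' @return list `gd` (a `geno_data`, one pseudo-chromosome), `pop` (true
#'   labels).
#' @export
simulate_divergent_pops <- function(n_per_pop = 100L, n_snps = 2000L,
                                    fst = 0.1, seed = 1L) {
  set.seed(seed)
  p0 <- stats::runif(n_snps, 0.1, 0.9)
  shape <- (1 - fst) / fst
  pmat <- cbind(stats::rbeta(n_snps, p0 * shape, (1 - p0) * shape),
                stats::rbeta(n_snps, p0 * shape, (1 - p0) * shape))
  pmat <- pmin(pmax(pmat, 0.01), 0.99)
  G <- matrix(NA_integer_, 2L * n_per_pop, n_snps)
  for (pop in 1:2) {
    rows <- ((pop - 1L) * n_per_pop + 1L):(pop * n_per_pop)
    G[rows, ] <- matrix(stats::rbinom(n_per_pop * n_snps, 2L,
                                      rep(pmat[, pop], each = n_per_pop)),
                        n_per_pop, n_snps)
  }
  rownames(G) <- sprintf("P%dI%03d", rep(1:2, each = n_per_pop),
                         rep(seq_len(n_per_pop), 2))
  map <- data.frame(snp_id = sprintf("s%05d", seq_len(n_snps)), chr = "1",
                    bp = as.integer(seq_len(n_snps) * 1000L),
                    allele1 = "B", allele2 = "A", stringsAsFactors = FALSE)
  list(gd = geno_data(G, map),
       pop = rep(c("pop1", "pop2"), each = n_per_pop))
}
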