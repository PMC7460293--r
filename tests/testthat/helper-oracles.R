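# Independent oracles used across the suite. These deliberately take the
# slow, literal route (memoised pairwise recursion, path enumeration,
# exhaustive interval search) so they share no code with the package
# implementations they check.

# random valid pedigree: founders first, then offspring drawn from earlier
# animals; optional fraction of unknown parents
rand_pedigree <- function(n, seed, n_founders = max(4L, n %/% 5L),
                          p_unknown = 0) {
  set.seed(seed)
  id <- sprintf("X%03d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  sex <- rep(c("M", "F"), length.out = n)
  year <- integer(n)
  year[seq_len(n_founders)] <- 2000L
  for (i in (n_founders + 1L):n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (runif(1) > p_unknown && length(males))
      sire[i] <- id[sample(males, 1L)]
    if (runif(1) > p_unknown && length(females))
      dam[i] <- id[sample(females, 1L)]
    py <- c(year[match(sire[i], id)], year[match(dam[i], id)])
    year[i] <- max(c(py, 2000L), na.rm = TRUE) + sample(1:5, 1L)
  }
  pedigree(id, sire, dam, year, sex)
}

# numerator relationship matrix by memoised pairwise recursion
# (Wright's rules), independent of the package's tabular/ML code
oracle_A <- function(ped) {
  n <- nrow(ped)
  A <- matrix(NA_real_, n, n)
  rel <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(A[i, j])) return(A[i, j])
    if (i == j) {
      v <- 1 + 0.5 * rel(ped$sire_idx[i], ped$dam_idx[i])
    } else {
      if (i < j) { tmp <- i; i <- j; j <- tmp }   # i is the younger (larger idx)
      v <- 0.5 * (rel(ped$sire_idx[i], j) + rel(ped$dam_idx[i], j))
    }
    A[i, j] <<- v; A[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) rel(i, j)
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# equivalent generations by explicit path enumeration
oracle_eqgen <- function(ped, i) {
  walk <- function(idx, k) {
    if (idx == 0L) return(0)
    (0.5)^k + walk(ped$sire_idx[idx], k + 1L) + walk(ped$dam_idx[idx], k + 1L)
  }
  walk(ped$sire_idx[i], 1L) + walk(ped$dam_idx[i], 1L)
}

# expected contribution of every animal to a reference set by explicit
# descent-path enumeration: share of ref genomes whose transmission paths
# pass through (or stop at) each animal
oracle_contributions <- function(ped, ref_ids) {
  n <- nrow(ped)
  total <- numeric(n)
  founder <- numeric(n)
  climb <- function(idx, w) {
    total[idx] <<- total[idx] + w
    s <- ped$sire_idx[idx]; d <- ped$dam_idx[idx]
    if (s > 0L) climb(s, w / 2) else founder[idx] <<- founder[idx] + w / 2
    if (d > 0L) climb(d, w / 2) else founder[idx] <<- founder[idx] + w / 2
  }
  for (r in match(ref_ids, ped$id)) climb(r, 1 / length(ref_ids))
  list(total = setNames(total, ped$id), founder = setNames(founder, ped$id))
}

# brute-force ROH: every interval [l, r] tested against the full criteria
# predicate (prefix sums make the per-interval test O(1)), then
# containment-maximal intervals kept
oracle_roh <- function(g, pos, par) {
  L <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  chet <- c(0L, cumsum(het))
  cmis <- c(0L, cumsum(mis))
  biggap <- c(diff(pos) > par$max_gap_bp, FALSE)
  ok <- list()
  for (l in seq_len(L)) {
    if (!hom[l]) next
    r <- l:L
    nsnp <- r - l + 1L
    len <- pos[r] - pos[l]
    pass <- hom[r] &
      nsnp >= par$min_snps &
      len >= par$min_length_bp &
      (chet[r + 1L] - chet[l]) <= par$max_het &
      (cmis[r + 1L] - cmis[l]) <= par$max_missing &
      cumsum(c(FALSE, biggap[r[-length(r)]])) == 0L &
      nsnp * par$density_bp_per_snp >= len
    ## for fixed l only the largest qualifying r can be containment-maximal
    if (any(pass)) ok[[length(ok) + 1L]] <- c(l, max(r[pass]))
  }
  if (!length(ok)) return(matrix(integer(0), 0, 2))
  M <- do.call(rbind, ok)
  keep <- vapply(seq_len(nrow(M)), function(i)
    !any(M[, 1] <= M[i, 1] & M[, 2] >= M[i, 2] &
           (M[, 1] != M[i, 1] | M[, 2] != M[i, 2])), logical(1))
  M[keep, , drop = FALSE]
}

# direct log-factorial HWE exact test (Levene/Haldane conditional
# distribution), independent of the package's ratio recurrence
oracle_hwe <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  na <- 2L * n_hom1 + n_het    # rare allele count
  hets <- seq(na %% 2L, min(na, 2L * n - na), by = 2L)
  logp <- vapply(hets, function(h) {
    r <- (na - h) / 2; cm <- n - h - r
    lgamma(n + 1) - lgamma(r + 1) - lgamma(cm + 1) - lgamma(h + 1) +
      h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  sum(p[p <= p[match(n_het, hets)] + 1e-12])
}

# simple HWE random-mating genotypes at given frequencies
hwe_genotypes <- function(n, p_vec, seed) {
  set.seed(seed)
  G <- sapply(p_vec, function(p) rbinom(n, 2L, p))
  rownames(G) <- sprintf("I%03d", seq_len(n))
  map <- data.frame(snp_id = sprintf("s%04d", seq_along(p_vec)), chr = "1",
                    bp = as.integer(seq_along(p_vec) * 50000L),
                    allele1 = "B", allele2 = "A", stringsAsFactors = FALSE)
  herdvar:::geno_data(G, map)
}

make_gd <- function(G, chr, bp) {
  map <- data.frame(snp_id = sprintf("m%04d", seq_len(ncol(G))),
                    chr = as.character(chr), bp = as.integer(bp),
                    allele1 = "B", allele2 = "A", stringsAsFactors = FALSE)
  herdvar:::geno_data(G, map)
}
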