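## Population structure: admixture-style ancestry by masked non-negative
## matrix factorisation on one-hot genotypes, cross-entropy model choice,
## identity-by-state distances, k-nearest-neighbour networks, subpopulation
## assignment, and per-subpopulation diversity comparison.

## one-hot encode dosages: n x 3L matrix (classes 0,1,2), NA rows of zeros
one_hot_geno <- function(G) {
  n <- nrow(G); L <- ncol(G)
  X <- matrix(0, n, 3L * L)
  for (cls in 0:2) {
    hit <- !is.na(G) & G == cls
    X[, seq(cls + 1L, 3L * L, by = 3L)][hit] <- 1
  }
  X
}

#' Ancestry estimation by masked non-negative matrix factorisation
#'
#' Genotypes are one-hot encoded (three classes per locus) and factorised as
#' \eqn{X \approx Q G} with Q rows on the probability simplex (individual
#' ancestry proportions) and per-component, per-locus genotype-class
#' probabilities in G, using weighted multiplicative updates. A fraction of
#' the non-missing entries is masked before fitting; the held-out
#' cross-entropy of the masked entries scores each run, and the best of
#' `n_runs` is returned.
#'
#' @param gd a `geno_data`.
#' @param K number of ancestral components.
#' @param n_runs independent random restarts.
#' @param mask_fraction fraction of non-missing genotype entries held out.
#' @param seed integer seed.
#' @param n_iter multiplicative-update iterations per run.
#' @param ridge small regularisation added to update denominators.
#' @return list of class `ancestry_fit`: `Q` (n x K, rownames = ids),
#'   `Gf`, `K`, `cross_entropy`, `loss_trace`, `seed`, `run`.
#' @export
ancestry_nmf <- function(gd, K, n_runs = 7L, mask_fraction = 0.05,
                         seed = 1L, n_iter = 150L, ridge = 1e-8) {
  G <- gd$G
  n <- nrow(G); L <- ncol(G)
  if (K > n) stop("K exceeds the number of individuals")
  X <- one_hot_geno(G)
  obs_locus <- !is.na(G)                      # n x L
  best <- NULL
  for (run in seq_len(n_runs)) {
    set.seed(seed + 1000L * (run - 1L))
    ## mask: per (individual, locus) cells among non-missing
    obs_cells <- which(obs_locus)
    n_mask <- max(1L, round(mask_fraction * length(obs_cells)))
    masked <- sample(obs_cells, n_mask)
    train_locus <- obs_locus
    train_locus[masked] <- FALSE
    ## weights expanded to the 3 classes of each locus
    W <- matrix(0, n, 3L * L)
    for (cls in 0:2) W[, seq(cls + 1L, 3L * L, by = 3L)] <- train_locus

    if (K == 1L) {
      Q <- matrix(1, n, 1L)
      Gf <- matrix(colSums(W * X) / pmax(colSums(W), 1), 1L, 3L * L)
      fit <- list(Q = Q, Gf = Gf, loss = numeric(0))
    } else {
      fit <- nmf_fit(X, W, K, n_iter = n_iter, ridge = ridge)
    }
    ce <- masked_cross_entropy(fit$Q, fit$Gf, G, masked)
    if (is.null(best) || ce < best$cross_entropy) {
      best <- structure(list(Q = fit$Q, Gf = fit$Gf, K = K,
                             cross_entropy = ce, loss_trace = fit$loss,
                             seed = seed, run = run),
                        class = "ancestry_fit")
    }
  }
  rownames(best$Q) <- rownames(G)
  best
}

## weighted multiplicative-update NMF with simplex-normalised Q rows and
## per-locus probability triplets in Gf
nmf_fit <- function(X, W, K, n_iter = 150L, ridge = 1e-8) {
  n <- nrow(X); M <- ncol(X); L <- M / 3L
  Q <- matrix(stats::runif(n * K, 0.1, 1), n, K)
  Q <- Q / rowSums(Q)
  Gf <- matrix(stats::runif(K * M, 0.1, 1), K, M)
  Gf <- normalize_triplets(Gf)
  loss <- numeric(n_iter)
  WX <- W * X
  for (it in seq_len(n_iter)) {
    P <- Q %*% Gf
    Q <- Q * ((WX %*% t(Gf)) / ((W * P) %*% t(Gf) + ridge))
    Q <- pmax(Q, 1e-9)
    Q <- Q / rowSums(Q)
    P <- Q %*% Gf
    Gf <- Gf * ((t(Q) %*% WX) / (t(Q) %*% (W * P) + ridge))
    Gf <- normalize_triplets(pmax(Gf, 1e-9))
    P <- Q %*% Gf
    loss[it] <- sum(W * (X - P)^2)
    if (it > 5L && abs(loss[it - 1L] - loss[it]) < 1e-5 * (loss[it] + 1))
      { loss <- loss[seq_len(it)]; break }
  }
  list(Q = Q, Gf = Gf, loss = loss)
}

normalize_triplets <- function(Gf) {
  M <- ncol(Gf)
  for (cls in 0:2) {
    if (cls == 0) tot <- Gf[, seq(1, M, 3), drop = FALSE] * 0
    tot <- tot + Gf[, seq(cls + 1, M, 3), drop = FALSE]
  }
  for (cls in 0:2) {
    idx <- seq(cls + 1, M, 3)
    Gf[, idx] <- Gf[, idx, drop = FALSE] / tot
  }
  Gf
}

## cross-entropy of true genotype classes at masked (ind, locus) cells
masked_cross_entropy <- function(Q, Gf, G, masked_cells) {
  n <- nrow(G)
  idx <- masked_cells - 1L
  i <- idx %% n + 1L
  l <- idx %/% n + 1L
  cls <- G[masked_cells]
  base <- 3L * (l - 1L)
  p0 <- pmax(rowSums(Q[i, , drop = FALSE] * t(Gf[, base + 1L, drop = FALSE])), 1e-12)
  p1 <- pmax(rowSums(Q[i, , drop = FALSE] * t(Gf[, base + 2L, drop = FALSE])), 1e-12)
  p2 <- pmax(rowSums(Q[i, , drop = FALSE] * t(Gf[, base + 3L, drop = FALSE])), 1e-12)
  tot <- p0 + p1 + p2
  p <- ifelse(cls == 0L, p0, ifelse(cls == 1L, p1, p2)) / tot
  -mean(log(p))
}

#' Choose the number of ancestral components by cross-entropy
#'
#' @param ce named numeric vector: best-run cross-entropy per K (names = K).
#' @return list `K` (argmin; ties resolved to the smallest K and flagged),
#'   `table` (data.frame K, cross_entropy), `tie`.
#' @export
choose_k <- function(ce) {
  if (length(ce) < 2L) stop("need cross-entropies for at least two K values")
  Ks <- as.integer(names(ce))
  best <- min(ce)
  hits <- Ks[ce <= best + 1e-12]
  list(K = min(hits), table = data.frame(K = Ks, cross_entropy = as.numeric(ce)),
       tie = length(hits) > 1L)
}

#' Identity-by-state allele-sharing distance matrix
#'
#' For each pair, the per-locus proportion of shared alleles is
#' 1, 0.5 or 0 for dosage differences 0, 1, 2; the distance is one minus the
#' mean over loci where both individuals are genotyped.
#'
#' @param gd a `geno_data`.
#' @param min_overlap minimum shared loci per pair.
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibs_distance <- function(gd, min_overlap = 1L) {
  G <- gd$G
  obs <- (!is.na(G)) * 1
  I0 <- (obs == 1 & G == 0); I0[is.na(G)] <- FALSE
  I1 <- (obs == 1 & G == 1); I1[is.na(G)] <- FALSE
  I2 <- (obs == 1 & G == 2); I2[is.na(G)] <- FALSE
  storage.mode(I0) <- "numeric"; storage.mode(I1) <- "numeric"
  storage.mode(I2) <- "numeric"
  n_overlap <- obs %*% t(obs)
  abs_diff <- 2 * (I0 %*% t(I2) + I2 %*% t(I0)) +
    (I1 %*% t(I0 + I2) + (I0 + I2) %*% t(I1))
  if (any(n_overlap[upper.tri(n_overlap)] < min_overlap))
    stop("pairs with insufficient genotype overlap")
  D <- abs_diff / (2 * n_overlap)
  diag(D) <- 0
  dimnames(D) <- list(rownames(G), rownames(G))
  D
}

#' k-nearest-neighbour population network
#'
#' Directed k-nearest edges (ties broken by id order) symmetrised to an
#' undirected graph; connected components and modularity-based communities
#' are attached.
#'
#' @param D symmetric distance matrix.
#' @param k neighbours per node.
#' @return list of class `pop_network`: `graph` (igraph), `edges`
#'   (data.frame from, to, distance), `components`, `community`, `degree`,
#'   `isolated`.
#' @export
knn_network <- function(D, k = 10L) {
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of individuals")
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], ids)      # distance, then id for ties
    ord <- ord[ord != i][seq_len(k)]
    from <- c(from, rep(i, k)); to <- c(to, ord)
  }
  a <- pmin(from, to); b <- pmax(from, to)
  und <- !duplicated(cbind(a, b))
  edges <- data.frame(from = ids[a[und]], to = ids[b[und]],
                      distance = D[cbind(a[und], b[und])],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  igraph::E(g)$weight <- 1 - edges$distance
  comp <- igraph::components(g)
  comm <- igraph::cluster_louvain(g)
  deg <- igraph::degree(g)
  structure(list(graph = g, edges = edges,
                 components = stats::setNames(comp$membership, ids),
                 community = stats::setNames(igraph::membership(comm)[ids], ids),
                 degree = deg, isolated = ids[deg == 0]),
            class = "pop_network")
}

#' Assign individuals to subpopulations from ancestry proportions
#'
#' Argmax over ancestry components; exact ties go to the lower component
#' index and are flagged.
#'
#' @param Q ancestry matrix (rows sum to 1, rownames = ids) or an
#'   `ancestry_fit`.
#' @return data.frame `id`, `subpop` (factor `subpop1..subpopK`), `max_q`,
#'   `tie`.
#' @export
assign_subpops <- function(Q) {
  if (inherits(Q, "ancestry_fit")) Q <- Q$Q
  k <- max.col(Q, ties.method = "first")
  mx <- Q[cbind(seq_len(nrow(Q)), k)]
  tie <- rowSums(abs(Q - mx) < 1e-12) > 1L
  data.frame(id = rownames(Q),
             subpop = factor(paste0("subpop", k),
                             levels = paste0("subpop", seq_len(ncol(Q)))),
             max_q = mx, tie = tie, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare subpopulations: gene origin and genomic inbreeding
#'
#' Runs the probability-of-gene-origin analysis with each subpopulation as
#' the reference, and summarises the F_roh distribution per subpopulation.
#'
#' @param ped a `herd_pedigree` containing all genotyped individuals.
#' @param assignment output of [assign_subpops()].
#' @param froh_table output of [froh()] (optional).
#' @return list per subpopulation of `gene_origin` results and `f_roh`
#'   summaries, plus `a50_overlap`: shared a50 ancestors between every pair.
#' @export
subpop_diversity <- function(ped, assignment, froh_table = NULL) {
  missing_ids <- setdiff(assignment$id, ped$id)
  if (length(missing_ids))
    stop("genotyped individuals absent from pedigree: ",
         paste(missing_ids, collapse = ", "))
  labs <- levels(assignment$subpop)
  labs <- labs[labs %in% assignment$subpop]
  per <- lapply(labs, function(lb) {
    ids <- assignment$id[assignment$subpop == lb]
    go <- gene_origin(ped, ids)
    fr <- NULL
    if (!is.null(froh_table)) {
      v <- froh_table$f_roh[froh_table$id %in% ids]
      fr <- list(mean = mean(v), sd = stats::sd(v), n = length(v))
    }
    list(n = length(ids), gene_origin = go, f_roh = fr)
  })
  names(per) <- labs
  overlap <- list()
  if (length(labs) >= 2L) {
    for (i in seq_len(length(labs) - 1L)) for (j in (i + 1L):length(labs)) {
      key <- paste(labs[i], labs[j], sep = "|")
      overlap[[key]] <- intersect(per[[i]]$gene_origin$summary$a50_ids,
                                  per[[j]]$gene_origin$summary$a50_ids)
    }
  }
  list(subpops = per, a50_overlap = overlap)
}
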