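## Probability of gene origin: expected founder contributions, marginal
## ancestor contributions (greedy selection with path blocking), and the
## derived effective numbers f_e, f_a, the fa/fe ratio and a50.

## Upward diffusion of reference-genome mass through the pedigree.
## Each reference animal injects 1/|R|; every animal passes half its mass to
## each KNOWN parent. `blocked` animals absorb mass (their parents are treated
## as unknown and they retain nothing as founder).
## Returns list(total = mass arriving at each animal,
##              founder = mass retained through unknown parent slots).
gene_flow <- function(ped, ref_idx, blocked = integer(0)) {
  n <- nrow(ped)
  m <- numeric(n)
  m[ref_idx] <- m[ref_idx] + 1 / length(ref_idx)
  founder <- numeric(n)
  is_blocked <- rep(FALSE, n); is_blocked[blocked] <- TRUE
  for (i in rev(seq_len(n))) {        # children before parents
    if (m[i] == 0) next
    if (is_blocked[i]) next           # absorbed: already explained
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    half <- m[i] / 2
    if (s > 0L) m[s] <- m[s] + half else founder[i] <- founder[i] + half
    if (d > 0L) m[d] <- m[d] + half else founder[i] <- founder[i] + half
  }
  list(total = m, founder = founder)
}

#' Expected founder contributions to a reference population
#'
#' A founder is any animal with at least one unknown parent; the unknown slot
#' terminates gene flow at that animal. Contributions are expected genomic
#' shares: each reference animal owes 1/2 of its genome to each parent,
#' recursively.
#'
#' @param ped a `herd_pedigree`.
#' @param reference_ids ids of the reference population.
#' @return data.frame `id`, `p` (expected contribution), sorted decreasing;
#'   contributions sum to 1.
#' @export
founder_contributions <- function(ped, reference_ids) {
  ref_idx <- match(reference_ids, ped$id)
  if (!length(ref_idx)) stop("empty reference population")
  if (anyNA(ref_idx))
    stop("reference ids missing from pedigree: ",
         paste(reference_ids[is.na(ref_idx)], collapse = ", "))
  fl <- gene_flow(ped, ref_idx)
  keep <- fl$founder > 0
  out <- data.frame(id = ped$id[keep], p = fl$founder[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$p, out$id), ]
  rownames(out) <- NULL
  out
}

## Fraction of a gene lineage starting upward at each animal that terminates
## at an unselected founder slot (selected ancestors absorb their lineages).
unexplained_fraction <- function(ped, blocked = integer(0)) {
  n <- nrow(ped)
  e <- numeric(n)
  is_blocked <- rep(FALSE, n); is_blocked[blocked] <- TRUE
  for (i in seq_len(n)) {               # parents first
    if (is_blocked[i]) { e[i] <- 0; next }
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    e[i] <- (if (s > 0L) e[s] else 1) / 2 + (if (d > 0L) e[d] else 1) / 2
  }
  e
}

#' Marginal ancestor contributions (greedy bottleneck analysis)
#'
#' Iteratively selects the ancestor (founder or not) with the largest
#' contribution to the reference population not yet explained by previously
#' selected ancestors. A candidate's marginal contribution is the expected
#' share of reference genes that pass through it and are not intercepted by
#' an already-selected ancestor: selected ancestors absorb the gene flow
#' (their parents are treated as unknown), both below and above the
#' candidate.
#'
#' @param ped a `herd_pedigree`.
#' @param reference_ids reference population ids.
#' @param tol stop once the residual unexplained contribution falls below this.
#' @param max_ancestors optional cap on the number selected.
#' @return data.frame `rank`, `id`, `q` (marginal contribution), `cum_q`.
#' @export
marginal_ancestor_contributions <- function(ped, reference_ids, tol = 1e-6,
                                            max_ancestors = Inf) {
  ref_idx <- match(reference_ids, ped$id)
  if (!length(ref_idx)) stop("empty reference population")
  if (anyNA(ref_idx)) stop("reference ids missing from pedigree")
  raw <- gene_flow(ped, ref_idx)$total   # tie-break key: unblocked contribution
  selected <- integer(0)
  q <- numeric(0)
  explained <- 0
  rounds <- 0L
  while (explained < 1 - tol && length(q) < max_ancestors) {
    rounds <- rounds + 1L
    if (rounds > nrow(ped) + 1L)
      stop("ancestor selection failed to converge (internal error)")
    fl <- gene_flow(ped, ref_idx, blocked = selected)
    cand <- fl$total * unexplained_fraction(ped, blocked = selected)
    cand[selected] <- -Inf
    best <- max(cand)
    if (!is.finite(best) || best <= tol) break
    ties <- which(cand >= best - 1e-12)
    if (length(ties) > 1L) {       # higher raw contribution, then id order
      ties <- ties[order(-raw[ties], ped$id[ties])]
    }
    pick <- ties[1L]
    selected <- c(selected, pick)
    q <- c(q, cand[pick])
    explained <- explained + cand[pick]
  }
  data.frame(rank = seq_along(q), id = ped$id[selected], q = q,
             cum_q = cumsum(q), stringsAsFactors = FALSE)
}

#' Summarise probability-of-gene-origin statistics
#'
#' Effective number of founders \eqn{f_e = 1/\sum_j p_j^2}, effective number
#' of ancestors \eqn{f_a = 1/\sum_k q_k^2}, their ratio, and a50: the smallest
#' number of top-ranked ancestors jointly explaining `target_fraction` of the
#' reference gene pool.
#'
#' @param founders data.frame from [founder_contributions()].
#' @param ancestors data.frame from [marginal_ancestor_contributions()].
#' @param target_fraction cumulative contribution threshold for a50.
#' @return list with `f_e`, `f_a`, `ratio_fa_fe`, `a50`, `a50_ids`,
#'   `n_founders`, `n_ancestors`, `a50_incomplete` (TRUE when even all
#'   ancestors do not reach the target).
#' @export
gene_origin_summary <- function(founders, ancestors, target_fraction = 0.5) {
  f_e <- 1 / sum(founders$p^2)
  f_a <- 1 / sum(ancestors$q^2)
  reach <- which(ancestors$cum_q >= target_fraction)
  incomplete <- !length(reach)
  a50 <- if (incomplete) nrow(ancestors) else reach[1L]
  list(
    f_e = f_e, f_a = f_a, ratio_fa_fe = f_a / f_e,
    a50 = a50, a50_ids = ancestors$id[seq_len(a50)],
    n_founders = nrow(founders), n_ancestors = nrow(ancestors),
    a50_incomplete = incomplete
  )
}

#' One-call gene-origin analysis for a reference population
#'
#' @inheritParams marginal_ancestor_contributions
#' @param target_fraction see [gene_origin_summary()].
#' @return list with `founders`, `ancestors`, and `summary`.
#' @export
gene_origin <- function(ped, reference_ids, tol = 1e-6, target_fraction = 0.5) {
  founders <- founder_contributions(ped, reference_ids)
  ancestors <- marginal_ancestor_contributions(ped, reference_ids, tol = tol)
  list(founders = founders, ancestors = ancestors,
       summary = gene_origin_summary(founders, ancestors, target_fraction))
}
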