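## Pedigree inbreeding and relatedness.
##
## F_trad: Meuwissen & Luo ancestor-tracing algorithm (exact diagonal of the
##   numerator relationship matrix minus 1).
## F_rec: recursive estimator for incomplete pedigrees; an animal with any
##   unknown parent is assigned the mean inbreeding of known-parent newborns
##   of its birth-year cohort, and the assigned value propagates to
##   descendants through the relationship recursion.
## AR: average relatedness, the mean of an individual's row of A, computed
##   by the top-down/bottom-up contribution recursions (no dense A needed).

## ancestor set of animal i (excluding i), as indices
ancestor_set <- function(ped, i) {
  seen <- logical(nrow(ped))
  stack <- c(ped$sire_idx[i], ped$dam_idx[i])
  stack <- stack[stack > 0L]
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    for (p in c(ped$sire_idx[v], ped$dam_idx[v]))
      if (p > 0L && !seen[p]) stack <- c(stack, p)
  }
  which(seen)
}

## Mendelian sampling variance D given parental F (NA = unknown parent)
mendelian_d <- function(Fs, Fd) {
  base <- 0.5
  base + 0.25 * (is.na(Fs) + is.na(Fd)) -
    0.25 * (ifelse(is.na(Fs), 0, Fs) + ifelse(is.na(Fd), 0, Fd))
}

#' Pedigree inbreeding by the Meuwissen--Luo algorithm
#'
#' Computes per-animal inbreeding coefficients equal to the diagonal of the
#' numerator relationship matrix minus one, tracing each animal's ancestor
#' paths with the L/D decomposition of A. Unknown parents contribute nothing.
#'
#' @param ped a `herd_pedigree`.
#' @return named numeric vector `F` (pedigree order).
#' @export
meuwissen_luo_F <- function(ped) {
  n <- nrow(ped)
  Fv <- numeric(n)
  D <- numeric(n)
  Lw <- numeric(n)     # scratch: L-row weights for the current animal
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    Fs <- if (s > 0L) Fv[s] else NA_real_
    Fd <- if (d > 0L) Fv[d] else NA_real_
    D[i] <- mendelian_d(Fs, Fd)
    if (s == 0L || d == 0L) { Fv[i] <- 0; next }
    anc <- sort(c(i, ancestor_set(ped, i)), decreasing = TRUE)
    Lw[anc] <- 0
    Lw[i] <- 1
    acc <- 0
    for (j in anc) {
      lj <- Lw[j]
      if (lj == 0) next
      acc <- acc + lj * lj * D[j]
      sj <- ped$sire_idx[j]; dj <- ped$dam_idx[j]
      if (sj > 0L) Lw[sj] <- Lw[sj] + 0.5 * lj
      if (dj > 0L) Lw[dj] <- Lw[dj] + 0.5 * lj
    }
    Fv[i] <- acc - 1
  }
  stats::setNames(Fv, ped$id)
}

## Dense numerator relationship matrix by the tabular method.
## diag_F: optional per-animal inbreeding overriding 0.5*a(s,d) on the
## diagonal (used by the recursive estimator).
tabular_A <- function(ped, diag_F = NULL) {
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    Fi <- if (!is.null(diag_F)) diag_F[i]
          else if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    A[i, i] <- 1 + Fi
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Recursive inbreeding for incomplete pedigrees
#'
#' Animals with at least one unknown parent are assigned the average
#' inbreeding of known-parent newborns of their birth-year cohort; the
#' assignment is iterated to a fixed point because cohort means depend on the
#' assigned values downstream. Animals with a fully known pedigree get the
#' standard \eqn{F = a_{sd}/2}, evaluated on a relationship matrix whose
#' diagonal carries the assigned inbreeding (so surrogate inbreeding
#' propagates to descendants).
#'
#' @param ped a `herd_pedigree`.
#' @param max_rounds,tol outer-iteration controls (max absolute change in F).
#' @return named numeric vector `F_rec` with attributes `converged` and
#'   `iterations`.
#' @export
recursive_F <- function(ped, max_rounds = 20L, tol = 1e-6) {
  n <- nrow(ped)
  unknown <- ped$sire_idx == 0L | ped$dam_idx == 0L
  Fv <- meuwissen_luo_F(ped)
  converged <- FALSE
  iter <- 0L
  for (round in seq_len(max_rounds)) {
    iter <- round
    ## cohort means over known-parent newborns of the same birth year
    yr_mean <- function(y) {
      if (is.na(y)) {
        vals <- Fv[!unknown]
        return(if (length(vals)) mean(vals) else 0)
      }
      sel <- !unknown & !is.na(ped$birth_year) & ped$birth_year == y
      if (!any(sel)) 0 else mean(Fv[sel])
    }
    Fnew <- numeric(n)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        row <- numeric(i - 1L)
        if (s > 0L) row <- row + 0.5 * A[s, j]
        if (d > 0L) row <- row + 0.5 * A[d, j]
        A[i, j] <- row
        A[j, i] <- row
      }
      Fnew[i] <- if (unknown[i]) yr_mean(ped$birth_year[i])
                 else 0.5 * A[s, d]
      A[i, i] <- 1 + Fnew[i]
    }
    delta <- max(abs(Fnew - Fv))
    Fv <- Fnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("recursive_F did not converge in ", max_rounds,
                          " rounds")
  out <- stats::setNames(Fv, ped$id)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  out
}

#' Average relatedness with the whole population
#'
#' Mean of each individual's row of the numerator relationship matrix over all
#' n animals (self term included). Computed without forming A, via the
#' \eqn{A = T D T'} decomposition: column sums of T by a bottom-up recursion,
#' then one top-down pass.
#'
#' @param ped a `herd_pedigree`.
#' @return named numeric vector `AR`.
#' @export
average_relatedness <- function(ped) {
  n <- nrow(ped)
  Fv <- meuwissen_luo_F(ped)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    D[i] <- mendelian_d(if (s > 0L) Fv[s] else NA_real_,
                        if (d > 0L) Fv[d] else NA_real_)
  }
  ## q = T'1 (total descendant flow): q_i = 1 + sum over children c of q_c/2
  q <- rep(1, n)
  for (i in rev(seq_len(n))) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (s > 0L) q[s] <- q[s] + 0.5 * q[i]
    if (d > 0L) q[d] <- q[d] + 0.5 * q[i]
  }
  ## r = T (D q): r_i = D_i q_i + (r_s + r_d)/2 ; AR = r / n
  r <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    r[i] <- D[i] * q[i]
    if (s > 0L) r[i] <- r[i] + 0.5 * r[s]
    if (d > 0L) r[i] <- r[i] + 0.5 * r[d]
  }
  stats::setNames(r / n, ped$id)
}

#' Individual rate of inbreeding from pedigree depth
#'
#' \eqn{\Delta F_i = 1 - (1 - F_i)^{1/(EqGen_i - 1)}}. Animals with
#' `EqGen <= 1` get 0 (flagged via attribute).
#'
#' @param F_trad named inbreeding vector.
#' @param eqgen named equivalent-generations vector (same order).
#' @return named numeric vector `delta_F` with attribute `shallow`
#'   (logical: EqGen <= 1, ΔF forced to 0).
#' @export
individual_delta_F <- function(F_trad, eqgen) {
  shallow <- eqgen <= 1
  dF <- ifelse(shallow, 0,
               ifelse(F_trad >= 1, 1, 1 - (1 - F_trad)^(1 / (eqgen - 1))))
  out <- stats::setNames(as.numeric(dF), names(F_trad))
  attr(out, "shallow") <- shallow
  out
}

#' Effective population size from the mean rate of inbreeding
#'
#' \eqn{N_e = 1/(2\bar{\Delta F})}; undefined (NA) when the mean rate is not
#' positive.
#'
#' @param mean_dF mean individual rate of inbreeding.
#' @return numeric Ne (NA if undefined).
#' @export
ne_from_delta_F <- function(mean_dF) {
  if (!is.finite(mean_dF) || mean_dF <= 0) return(NA_real_)
  1 / (2 * mean_dF)
}

#' Full per-animal pedigree inbreeding table
#'
#' @param ped a `herd_pedigree`.
#' @return data.frame `id`, `birth_year`, `F_trad`, `F_rec`, `AR`, `eqgen`,
#'   `delta_F`.
#' @export
inbreeding_table <- function(ped) {
  Ft <- meuwissen_luo_F(ped)
  Fr <- recursive_F(ped)
  eq <- equivalent_generations(ped)
  dF <- individual_delta_F(Ft, eq)
  data.frame(
    id = ped$id, birth_year = ped$birth_year,
    F_trad = as.numeric(Ft), F_rec = as.numeric(Fr),
    AR = as.numeric(average_relatedness(ped)),
    eqgen = as.numeric(eq), delta_F = as.numeric(dF),
    stringsAsFactors = FALSE
  )
}

#' Per-decade pedigree diversity summary
#'
#' Groups animals by decade of birth (floor(year/10)*10) and reports cohort
#' size, mean AR, F_trad, F_rec and ΔF (as percentages) and the pedigree
#' effective population size per group and overall. Animals with EqGen <= 1
#' are excluded from the ΔF (hence Ne) means; decades with no animals are
#' omitted.
#'
#' @param ped a `herd_pedigree`.
#' @param inb optional precomputed [inbreeding_table()].
#' @param decade_width grouping width in years.
#' @return data.frame with one row per decade plus a `Total` row.
#' @export
decade_summary <- function(ped, inb = NULL, decade_width = 10) {
  if (is.null(inb)) inb <- inbreeding_table(ped)
  dated <- !is.na(inb$birth_year)
  x <- inb[dated, , drop = FALSE]
  x$decade <- floor(x$birth_year / decade_width) * decade_width
  mk_row <- function(label, g) {
    deep <- g$eqgen > 1
    mdF <- if (any(deep)) mean(g$delta_F[deep]) else NA_real_
    data.frame(
      decade = label, n = nrow(g),
      AR_pct = 100 * mean(g$AR), F_trad_pct = 100 * mean(g$F_trad),
      F_rec_pct = 100 * mean(g$F_rec), dF_pct = 100 * mdF,
      Ne_ped = if (is.na(mdF)) NA_real_ else ne_from_delta_F(mdF),
      stringsAsFactors = FALSE
    )
  }
  decs <- sort(unique(x$decade))
  rows <- lapply(decs, function(d) mk_row(as.character(d),
                                          x[x$decade == d, , drop = FALSE]))
  out <- do.call(rbind, c(rows, list(mk_row("Total", x))))
  rownames(out) <- NULL
  out
}
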