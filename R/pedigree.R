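#' @importFrom stats sd cor var rbinom rbeta runif rpois setNames aggregate na.omit
#' @importFrom utils read.table write.table head tail
NULL

UNKNOWN_TOKENS <- c("0", "", NA)

#' Construct a validated pedigree
#'
#' Builds a `herd_pedigree` object from per-animal records. Records are stored
#' in topological order (parents before offspring) with integer parent indices
#' for fast downstream recursions.
#'
#' @param animal_id character vector of unique animal identifiers.
#' @param sire_id,dam_id character vectors; `"0"`, `""` or `NA` mean unknown.
#' @param birth_year integer birth years (`NA` allowed).
#' @param sex `"M"`, `"F"` or `"U"` (unknown). Defaults to `"U"`.
#' @param origin `"native"` or `"imported"`. Defaults to `"native"`.
#' @param strict drop records flagged as parent-younger-than-child instead of
#'   keeping them flagged (mirrors studbook editing that removes inconsistent
#'   birth dates).
#'
#' @return A `herd_pedigree`: a data.frame with columns `id`, `sire`, `dam`,
#'   `birth_year`, `sex`, `origin`, `sire_idx`, `dam_idx` (0 = unknown),
#'   `flag_year` plus attribute `n`. Rows are topologically sorted.
#' @export
pedigree <- function(animal_id, sire_id, dam_id, birth_year = NA_integer_,
                     sex = "U", origin = "native", strict = FALSE) {
  id <- as.character(animal_id)
  n <- length(id)
  sire <- as.character(sire_id)
  dam <- as.character(dam_id)
  sire[sire %in% UNKNOWN_TOKENS | is.na(sire)] <- NA_character_
  dam[dam %in% UNKNOWN_TOKENS | is.na(dam)] <- NA_character_
  birth_year <- suppressWarnings(as.integer(rep_len(birth_year, n)))
  sex <- toupper(as.character(rep_len(sex, n)))
  sex[!sex %in% c("M", "F")] <- "U"
  origin <- as.character(rep_len(origin, n))
  origin[!origin %in% c("native", "imported")] <- "native"

  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate animal ids: ", paste(unique(dup), collapse = ", "))

  ## parents referenced but never listed become implicit founders
  missing_parents <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
  if (length(missing_parents)) {
    id <- c(id, missing_parents)
    sire <- c(sire, rep(NA_character_, length(missing_parents)))
    dam <- c(dam, rep(NA_character_, length(missing_parents)))
    birth_year <- c(birth_year, rep(NA_integer_, length(missing_parents)))
    sex <- c(sex, rep("U", length(missing_parents)))
    origin <- c(origin, rep("native", length(missing_parents)))
    n <- length(id)
  }

  sire_idx <- match(sire, id)
  dam_idx <- match(dam, id)

  ## sex consistency: a known-sex animal must not serve in the opposite role
  as_sire <- unique(stats::na.omit(sire))
  as_dam <- unique(stats::na.omit(dam))
  bad_sire <- as_sire[sex[match(as_sire, id)] == "F"]
  bad_dam <- as_dam[sex[match(as_dam, id)] == "M"]
  if (length(bad_sire) || length(bad_dam))
    stop("sex-inconsistent parent usage: ",
         paste(unique(c(bad_sire, bad_dam)), collapse = ", "))
  both_roles <- intersect(as_sire, as_dam)
  if (length(both_roles))
    warning("animals used as both sire and dam (unknown sex, e.g. selfing): ",
            paste(both_roles, collapse = ", "))

  ord <- ped_toposort(sire_idx, dam_idx, id)

  ped <- data.frame(
    id = id, sire = sire, dam = dam, birth_year = birth_year,
    sex = sex, origin = origin, stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(ped) <- NULL
  ped$sire_idx <- match(ped$sire, ped$id)
  ped$dam_idx <- match(ped$dam, ped$id)
  ped$sire_idx[is.na(ped$sire_idx)] <- 0L
  ped$dam_idx[is.na(ped$dam_idx)] <- 0L

  ## parent must be born before child (when both years known)
  flag <- rep(FALSE, nrow(ped))
  for (slot in c("sire_idx", "dam_idx")) {
    p <- ped[[slot]]
    has <- p > 0L
    py <- rep(NA_integer_, nrow(ped)); py[has] <- ped$birth_year[p[has]]
    bad <- !is.na(py) & !is.na(ped$birth_year) & py >= ped$birth_year
    flag <- flag | bad
  }
  if (any(flag)) {
    warning(sum(flag), " record(s) with parent not older than child (flagged)")
    if (strict) {
      keep <- !flag
      return(pedigree(ped$id[keep], ped$sire[keep], ped$dam[keep],
                      ped$birth_year[keep], ped$sex[keep], ped$origin[keep],
                      strict = FALSE))
    }
  }
  ped$flag_year <- flag
  class(ped) <- c("herd_pedigree", "data.frame")
  ped
}

## Kahn topological sort on parent links; stops with the offending cycle.
ped_toposort <- function(sire_idx, dam_idx, id) {
  n <- length(id)
  indeg <- integer(n)            # number of unplaced parents
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_idx[i], dam_idx[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  ord <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    cyc <- setdiff(seq_len(n), ord)
    stop("pedigree contains a cycle involving: ",
         paste(id[cyc], collapse = ", "))
  }
  ord
}

#' Read a pedigree from a delimited file
#'
#' Expects a header with columns `id`, `sire`, `dam` and optionally
#' `birth_year`, `sex`, `origin`. Both `"0"` and the empty string denote an
#' unknown parent. Comma- and tab-separated dialects are auto-detected.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @param strict see [pedigree()].
#' @return a `herd_pedigree`.
#' @export
read_pedigree <- function(path, sep = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          na.strings = character(0), check.names = FALSE,
                          comment.char = "")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id, sire, dam")
  pedigree(
    df$id, df$sire, df$dam,
    birth_year = if ("birth_year" %in% names(df)) df$birth_year else NA,
    sex = if ("sex" %in% names(df)) df$sex else "U",
    origin = if ("origin" %in% names(df)) df$origin else "native",
    strict = strict
  )
}

#' Write a pedigree in the canonical CSV dialect
#'
#' Unknown parents are written as `"0"`; reading the file back reproduces the
#' pedigree exactly.
#'
#' @param ped a `herd_pedigree`.
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    id = ped$id,
    sire = ifelse(is.na(ped$sire), "0", ped$sire),
    dam = ifelse(is.na(ped$dam), "0", ped$dam),
    birth_year = ifelse(is.na(ped$birth_year), "", ped$birth_year),
    sex = ped$sex, origin = ped$origin, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.herd_pedigree <- function(x, ...) {
  cat("herd_pedigree:", nrow(x), "animals,",
      sum(x$sire_idx == 0L & x$dam_idx == 0L), "founders")
  yr <- x$birth_year[!is.na(x$birth_year)]
  if (length(yr)) cat(", birth years", min(yr), "-", max(yr))
  cat("\n")
  invisible(x)
}

#' Pedigree completeness index
#'
#' Fraction of known parent slots per birth-year cohort, and the overall index
#' as the mean of yearly fractions weighted by the number of newborns.
#' Animals without a birth year are excluded from the index (their count is
#' reported).
#'
#' @param ped a `herd_pedigree`.
#' @return list with `per_year` (data.frame `birth_year`, `n_born`, `pc`),
#'   `overall_pc`, and `n_excluded_no_year`.
#' @export
pedigree_completeness <- function(ped) {
  if (nrow(ped) == 0L) stop("empty pedigree")
  has_year <- !is.na(ped$birth_year)
  dat <- ped[has_year, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no animal has a birth year")
  known <- (dat$sire_idx > 0L) + (dat$dam_idx > 0L)
  agg <- aggregate(cbind(known = known, one = rep(1L, nrow(dat))),
                   by = list(birth_year = dat$birth_year), FUN = sum)
  per_year <- data.frame(
    birth_year = agg$birth_year,
    n_born = agg$one,
    pc = agg$known / (2 * agg$one)
  )
  per_year <- per_year[order(per_year$birth_year), ]
  rownames(per_year) <- NULL
  overall <- sum(per_year$pc * per_year$n_born) / sum(per_year$n_born)
  list(per_year = per_year, overall_pc = overall,
       n_excluded_no_year = sum(!has_year))
}

#' Equivalent generations
#'
#' Pedigree depth per animal as the sum of \eqn{(1/2)^k} over all known
#' ancestors (k = 1 for parents, 2 for grandparents, ...), computed by the
#' recursion \eqn{EqGen_i = \sum_{p \in known\ parents} (1 + EqGen_p)/2}.
#'
#' @param ped a `herd_pedigree`.
#' @return named numeric vector of equivalent generations, one per animal.
#' @export
equivalent_generations <- function(ped) {
  n <- nrow(ped)
  eq <- numeric(n)
  for (i in seq_len(n)) {   # topological order: parents first
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    v <- 0
    if (s > 0L) v <- v + (1 + eq[s]) / 2
    if (d > 0L) v <- v + (1 + eq[d]) / 2
    eq[i] <- v
  }
  stats::setNames(eq, ped$id)
}

#' Generation lengths over the four gamete pathways
#'
#' Mean age of parents at offspring birth, split by sire--son, sire--daughter,
#' dam--son and dam--daughter pathways. Pairs with a missing birth year on
#' either side are skipped and counted.
#'
#' @param ped a `herd_pedigree`.
#' @return data.frame with rows `SS`, `SD`, `DS`, `DD`, `overall` and columns
#'   `mean`, `sd`, `n_pairs`, plus attribute `n_skipped_missing_year`.
#' @export
generation_lengths <- function(ped) {
  res <- data.frame(pathway = c("SS", "SD", "DS", "DD"),
                    mean = NA_real_, sd = NA_real_, n_pairs = 0L,
                    stringsAsFactors = FALSE)
  ages <- list(SS = numeric(0), SD = numeric(0),
               DS = numeric(0), DD = numeric(0))
  skipped <- 0L
  for (i in seq_len(nrow(ped))) {
    cy <- ped$birth_year[i]
    csex <- ped$sex[i]
    for (slot in c("sire_idx", "dam_idx")) {
      p <- ped[[slot]][i]
      if (p == 0L) next
      py <- ped$birth_year[p]
      if (is.na(cy) || is.na(py)) { skipped <- skipped + 1L; next }
      if (csex == "U") { skipped <- skipped + 1L; next }
      key <- paste0(if (slot == "sire_idx") "S" else "D",
                    if (csex == "M") "S" else "D")
      ages[[key]] <- c(ages[[key]], cy - py)
    }
  }
  for (k in seq_len(4L)) {
    a <- ages[[res$pathway[k]]]
    res$n_pairs[k] <- length(a)
    if (length(a)) {
      res$mean[k] <- mean(a)
      res$sd[k] <- if (length(a) > 1L) stats::sd(a) else NA_real_
    }
  }
  all_ages <- unlist(ages, use.names = FALSE)
  overall <- data.frame(pathway = "overall",
                        mean = if (length(all_ages)) mean(all_ages) else NA_real_,
                        sd = if (length(all_ages) > 1L) stats::sd(all_ages) else NA_real_,
                        n_pairs = length(all_ages), stringsAsFactors = FALSE)
  out <- rbind(res, overall)
  attr(out, "n_skipped_missing_year") <- skipped
  out
}

#' Define a reference population by birth-year window and origin
#'
#' @param ped a `herd_pedigree`.
#' @param year_from,year_to inclusive birth-year bounds.
#' @param exclude_origin origins to drop (e.g. `"imported"`).
#' @return character vector of animal ids.
#' @export
reference_population <- function(ped, year_from, year_to,
                                 exclude_origin = character(0)) {
  keep <- !is.na(ped$birth_year) &
    ped$birth_year >= year_from & ped$birth_year <= year_to &
    !(ped$origin %in% exclude_origin)
  ids <- ped$id[keep]
  if (!length(ids)) warning("reference population is empty")
  ids
}
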