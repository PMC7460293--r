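## ROH islands: per-SNP incidence of homozygous runs across individuals, and
## interval calling at a sharing threshold (candidate selection signatures).

#' Per-SNP ROH incidence track
#'
#' For every SNP of the map, counts the individuals carrying at least one ROH
#' covering its position.
#'
#' @param segments a `roh_segments` data.frame (from [detect_roh()]).
#' @param map marker map (`snp_id`, `chr`, `bp`).
#' @param individuals ids of all genotyped individuals (denominator).
#' @return data.frame `snp_id`, `chr`, `bp`, `n_in_roh`, `frac_in_roh`.
#' @export
roh_incidence <- function(segments, map, individuals) {
  bad <- setdiff(unique(segments$chr), unique(map$chr))
  if (length(bad))
    stop("segments on chromosomes absent from map: ", paste(bad, collapse = ", "))
  n <- length(individuals)
  out <- map[, c("snp_id", "chr", "bp")]
  out$n_in_roh <- 0L
  for (ch in unique(map$chr)) {
    msel <- which(map$chr == ch)
    pos <- map$bp[msel]
    seg <- segments[segments$chr == ch, , drop = FALSE]
    if (!nrow(seg)) next
    counts <- integer(length(pos))
    ## per individual, count each SNP at most once even with overlapping runs
    for (id in unique(seg$id)) {
      s <- seg[seg$id == id, , drop = FALSE]
      covered <- logical(length(pos))
      for (k in seq_len(nrow(s)))
        covered <- covered | (pos >= s$start_bp[k] & pos <= s$end_bp[k])
      counts <- counts + covered
    }
    out$n_in_roh[msel] <- counts
  }
  out$frac_in_roh <- out$n_in_roh / n
  attr(out, "n_individuals") <- n
  out
}

#' Call ROH islands from an incidence track
#'
#' Maximal runs of consecutive SNPs whose in-ROH fraction strictly exceeds
#' the sharing threshold; interval bounds are the first and last qualifying
#' SNP positions, and islands never span chromosomes.
#'
#' @param track output of [roh_incidence()].
#' @param threshold sharing threshold (strict `>`).
#' @param min_snps,min_length_bp optional floors (default off).
#' @return data.frame `chr`, `start_bp`, `end_bp`, `length_kb`, `n_snps`,
#'   `peak_frac`, `mean_frac`, `threshold`.
#' @export
call_islands <- function(track, threshold = 0.7, min_snps = 0L,
                         min_length_bp = 0) {
  res <- list()
  for (ch in unique(track$chr)) {
    tr <- track[track$chr == ch, , drop = FALSE]
    tr <- tr[order(tr$bp), , drop = FALSE]
    above <- tr$frac_in_roh > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- starts[k]; i2 <- ends[k]
      n_snps <- i2 - i1 + 1L
      len <- tr$bp[i2] - tr$bp[i1]
      if (n_snps < min_snps || len < min_length_bp) next
      res[[length(res) + 1L]] <- data.frame(
        chr = ch, start_bp = tr$bp[i1], end_bp = tr$bp[i2],
        length_kb = len / 1e3, n_snps = n_snps,
        peak_frac = max(tr$frac_in_roh[i1:i2]),
        mean_frac = mean(tr$frac_in_roh[i1:i2]),
        threshold = threshold, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chr = character(0), start_bp = integer(0), end_bp = integer(0),
               length_kb = numeric(0), n_snps = integer(0),
               peak_frac = numeric(0), mean_frac = numeric(0),
               threshold = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare two island sets
#'
#' Intervals sharing at least one base pair (same chromosome) are counted as
#' shared.
#'
#' @param set_a,set_b island data.frames from [call_islands()].
#' @return list `n_shared`, `shared_pairs` (data.frame of indices),
#'   `unique_a`, `unique_b` (row indices unique to each set).
#' @export
compare_island_sets <- function(set_a, set_b) {
  pairs <- list()
  hit_a <- rep(FALSE, nrow(set_a))
  hit_b <- rep(FALSE, nrow(set_b))
  for (i in seq_len(nrow(set_a))) for (j in seq_len(nrow(set_b))) {
    if (set_a$chr[i] == set_b$chr[j] &&
        set_a$start_bp[i] <= set_b$end_bp[j] &&
        set_b$start_bp[j] <= set_a$end_bp[i]) {
      pairs[[length(pairs) + 1L]] <- data.frame(a = i, b = j)
      hit_a[i] <- TRUE; hit_b[j] <- TRUE
    }
  }
  list(
    n_shared = sum(hit_a),
    shared_pairs = if (length(pairs)) do.call(rbind, pairs)
                   else data.frame(a = integer(0), b = integer(0)),
    unique_a = which(!hit_a),
    unique_b = which(!hit_b)
  )
}

#' Write islands as a BED file
#'
#' Converts internal 1-based inclusive coordinates to BED 0-based half-open.
#'
#' @param islands data.frame from [call_islands()].
#' @param path output path.
#' @export
write_islands_bed <- function(islands, path) {
  bed <- data.frame(chrom = islands$chr,
                    start = islands$start_bp - 1L,
                    end = islands$end_bp,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
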