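## PLINK-format genotype input/output.
##
## Internal representation: a list of class `geno_data` with
##   $G   integer matrix, individuals x SNPs, cells 0/1/2 = copies of the
##        counted allele (allele1), NA = missing; rownames = animal ids.
##   $map data.frame(snp_id, chr, bp, allele1, allele2); allele1 is the
##        counted allele, fixed to the minor allele at read time.

geno_data <- function(G, map) {
  stopifnot(ncol(G) == nrow(map))
  storage.mode(G) <- "integer"
  colnames(G) <- map$snp_id
  structure(list(G = G, map = map), class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat("geno_data:", nrow(x$G), "individuals x", ncol(x$G), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s)\n")
  invisible(x)
}

read_map_file <- function(path) {
  mp <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4) stop("MAP file needs 4 columns (chr, snp, cM, bp)")
  data.frame(snp_id = as.character(mp[[2]]), chr = as.character(mp[[1]]),
             bp = as.integer(mp[[4]]), stringsAsFactors = FALSE)
}

#' Read PLINK text PED/MAP genotypes
#'
#' Alleles must be coded A/C/G/T with 0 for missing. The counted allele of
#' each locus is set to the minor allele observed in the sample and frozen in
#' the returned map.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @return a `geno_data` list (`G` dosage matrix, `map` marker table).
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  map <- read_map_file(map_path)
  L <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  ids <- character(n)
  G <- matrix(NA_integer_, n, L)
  a1 <- matrix(NA_character_, n, L)
  a2 <- matrix(NA_character_, n, L)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != 6 + 2 * L)
      stop("PED row ", i, " has ", length(tk), " fields, expected ", 6 + 2 * L)
    ids[i] <- tk[2]
    al <- tk[-(1:6)]
    bad <- !al %in% c("A", "C", "G", "T", "0")
    if (any(bad)) stop("invalid allele code(s) in PED row ", i, ": ",
                       paste(unique(al[bad]), collapse = ", "))
    a1[i, ] <- al[seq(1, 2 * L, by = 2)]
    a2[i, ] <- al[seq(2, 2 * L, by = 2)]
  }
  allele1 <- character(L); allele2 <- character(L)
  for (j in seq_len(L)) {
    als <- c(a1[, j], a2[, j])
    als <- als[als != "0"]
    tab <- sort(table(als))
    if (length(tab) == 0L) { allele1[j] <- "0"; allele2[j] <- "0"; next }
    if (length(tab) > 2L) stop("SNP ", map$snp_id[j], " has >2 alleles")
    allele1[j] <- names(tab)[1L]                       # minor = counted
    allele2[j] <- if (length(tab) == 2L) names(tab)[2L] else "0"
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dos <- (a1[, j] == allele1[j]) + (a2[, j] == allele1[j])
    dos[miss] <- NA_integer_
    G[, j] <- dos
  }
  map$allele1 <- allele1
  map$allele2 <- allele2
  rownames(G) <- ids
  geno_data(G, map)
}

#' Write PLINK text PED/MAP files
#'
#' @param gd a `geno_data`.
#' @param prefix output prefix (`prefix.ped`, `prefix.map`).
#' @export
write_plink_text <- function(gd, prefix) {
  map <- gd$map
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, map$bp),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  G <- gd$G
  n <- nrow(G); L <- ncol(G)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    al <- character(2 * L)
    g <- G[i, ]
    c1 <- ifelse(is.na(g), "0", ifelse(g >= 1, map$allele1, map$allele2))
    c2 <- ifelse(is.na(g), "0", ifelse(g == 2, map$allele1, map$allele2))
    al[seq(1, 2 * L, 2)] <- c1
    al[seq(2, 2 * L, 2)] <- c2
    writeLines(paste(c("FAM", rownames(G)[i], "0", "0", "0", "-9", al),
                     collapse = " "), con)
  }
  invisible(prefix)
}

#' Read PLINK binary BED/BIM/FAM genotypes
#'
#' SNP-major .bed files only (the standard layout). Dosages count allele1 of
#' the .bim file.
#'
#' @param prefix path prefix (`prefix.bed`, `.bim`, `.fam`).
#' @return a `geno_data`.
#' @export
read_plink_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  map <- data.frame(snp_id = as.character(bim[[2]]), chr = as.character(bim[[1]]),
                    bp = as.integer(bim[[4]]), allele1 = as.character(bim[[5]]),
                    allele2 = as.character(bim[[6]]), stringsAsFactors = FALSE)
  n <- nrow(fam); L <- nrow(map)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * L)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  body <- raw[-(1:3)]
  bps <- ceiling(n / 4)
  ## 2-bit codes, little-endian within byte: 00 hom A1, 01 miss, 10 het, 11 hom A2
  lut <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      code <- v %% 4
      lut[b + 1, k] <- c(2L, NA_integer_, 1L, 0L)[code + 1]
      v <- v %/% 4
    }
  }
  G <- matrix(NA_integer_, n, L)
  idx <- rep(seq_len(bps), each = 4)[seq_len(n)]
  pos <- rep(1:4, times = bps)[seq_len(n)]
  for (j in seq_len(L)) {
    bytes <- as.integer(body[((j - 1) * bps + 1):(j * bps)])
    G[, j] <- lut[cbind(bytes[idx] + 1L, pos)]
  }
  rownames(G) <- as.character(fam[[2]])
  geno_data(G, map)
}

#' Write PLINK binary BED/BIM/FAM genotypes
#'
#' @param gd a `geno_data`.
#' @param prefix output prefix.
#' @export
write_plink_bed <- function(gd, prefix) {
  map <- gd$map; G <- gd$G
  n <- nrow(G); L <- ncol(G)
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, map$bp, map$allele1, map$allele2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame("FAM", rownames(G), 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  bps <- ceiling(n / 4)
  codes <- c(`2` = 0L, miss = 1L, `1` = 2L, `0` = 3L)
  out <- raw(3 + bps * L)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  mult <- 4L^(0:3)
  for (j in seq_len(L)) {
    g <- G[, j]
    code <- ifelse(is.na(g), 1L, ifelse(g == 2L, 0L, ifelse(g == 1L, 2L, 3L)))
    code <- c(code, rep(0L, bps * 4 - n))
    bytes <- colSums(matrix(code * mult, nrow = 4))
    out[(3 + (j - 1) * bps + 1):(3 + j * bps)] <- as.raw(bytes)
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read genotypes from PLINK text or binary files
#'
#' @param prefix path prefix; uses `prefix.bed` if present, else
#'   `prefix.ped`/`prefix.map`.
#' @return a `geno_data`.
#' @export
read_genotypes <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) read_plink_bed(prefix)
  else read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
}
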