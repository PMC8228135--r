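#' Read PLINK genotype files
#'
#' Reads either the text dialect (\code{.ped}/\code{.map}) or the binary
#' dialect (\code{.bed}/\code{.bim}/\code{.fam}, variant-major, magic bytes
#' \code{6c 1b 01}) into a \code{\link{genotype_dataset}}. Dosage counts the
#' A1 allele; unknown genotypes (allele code "0", or the 01 bit pattern in
#' .bed) become \code{NA}. For PED/MAP, which carries no allele columns, A1
#' is assigned as the minor allele with ties (and monomorphic markers) broken
#' lexicographically, so read -> write -> read is the identity. BIM allele
#' columns are honoured as given.
#'
#' The FAM/PED family ID column is used as the sample's group label.
#'
#' @param prefix path prefix (without extension).
#' @param dialect \code{"ped_map"} or \code{"bed_bim_fam"}.
#' @return A \code{\link{genotype_dataset}}, markers sorted by
#'   (chromosome, position).
#' @export
read_plink <- function(prefix, dialect = c("ped_map", "bed_bim_fam")) {
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") read_ped_map(prefix) else read_bed_bim_fam(prefix)
}

read_ped_map <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path))
    if (!file.exists(p)) stop("file not found: ", p)
  map <- utils::read.table(map_path, colClasses = "character")
  if (ncol(map) < 4) stop("malformed MAP: expected 4 columns")
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  sample_id <- character(n); group <- character(n)
  allele <- matrix(NA_character_, nrow = n, ncol = 2L * m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2L * m)
      stop("malformed PED line ", i, ": expected ", 6 + 2L * m,
           " fields, got ", length(f))
    group[i] <- f[1]
    sample_id[i] <- f[2]
    allele[i, ] <- f[-(1:6)]
  }
  allele[allele == "0"] <- NA_character_
  a1 <- character(m); a2 <- character(m)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    al1 <- allele[, 2L * j - 1L]; al2 <- allele[, 2L * j]
    # half-missing genotypes are treated as missing
    miss <- is.na(al1) | is.na(al2)
    al1[miss] <- NA; al2[miss] <- NA
    tab <- sort(table(c(al1, al2)), decreasing = TRUE)
    alleles <- names(tab)
    if (length(alleles) > 2)
      stop("non-biallelic marker '", map[j, 2], "': alleles ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0) {          # fully missing marker
      a1[j] <- "0"; a2[j] <- "0"
      next
    }
    if (length(alleles) == 1) alleles <- c(alleles, "0")
    # minor allele counted; ties broken lexicographically
    if (tab[[1]] == tab[[length(tab)]] && length(tab) == 2)
      alleles <- sort(alleles)
    else
      alleles <- rev(alleles)            # least frequent first
    a1[j] <- alleles[1]; a2[j] <- alleles[2]
    geno[, j] <- (al1 == a1[j]) + (al2 == a1[j])
  }
  markers <- data.frame(marker_id = map[, 2], chromosome = map[, 1],
                        position = as.integer(map[, 4]),
                        a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, group = group,
                        stringsAsFactors = FALSE)
  genotype_dataset(geno, markers, samples)
}

read_bed_bim_fam <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)
  bim <- utils::read.table(paths[2], colClasses = "character")
  if (ncol(bim) != 6) stop("malformed BIM: expected 6 columns")
  fam <- utils::read.table(paths[3], colClasses = "character")
  if (ncol(fam) < 2) stop("malformed FAM: expected >=2 columns")
  m <- nrow(bim); n <- nrow(fam)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only variant-major .bed files are supported")
  bpm <- ceiling(n / 4)                  # bytes per marker
  if (length(raw) - 3L != bpm * m)
    stop("dimension mismatch: .bed payload is ", length(raw) - 3L,
         " bytes, expected ", bpm * m, " for ", n, " samples x ", m, " markers")
  body <- raw[-(1:3)]
  # unpack 2-bit genotype codes, sample-fastest within marker
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  codes <- bits[seq(1, 8, by = 2), , drop = FALSE] +
           2L * bits[seq(2, 8, by = 2), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = 4L * bpm)[seq_len(n), , drop = FALSE]
  # 00 -> hom A1 (dosage 2), 10 (code 2) -> het, 11 (code 3) -> hom A2, 01 -> NA
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  geno[codes == 0L] <- 2L
  geno[codes == 2L] <- 1L
  geno[codes == 3L] <- 0L
  markers <- data.frame(marker_id = bim[, 2], chromosome = bim[, 1],
                        position = as.integer(bim[, 4]),
                        a1 = bim[, 5], a2 = bim[, 6], stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = fam[, 2], group = fam[, 1],
                        stringsAsFactors = FALSE)
  genotype_dataset(geno, markers, samples)
}

#' Write PLINK genotype files
#'
#' Writes a \code{\link{genotype_dataset}} as PED/MAP or BED/BIM/FAM
#' (variant-major). The group label goes into the family ID column.
#'
#' @param ds a \code{genotype_dataset}.
#' @param prefix output path prefix.
#' @param dialect \code{"ped_map"} or \code{"bed_bim_fam"}.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(ds, prefix, dialect = c("ped_map", "bed_bim_fam")) {
  dialect <- match.arg(dialect)
  mk <- ds$markers
  if (dialect == "ped_map") {
    map <- data.frame(mk$chromosome, mk$marker_id, 0L, mk$position)
    utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    n <- n_samples(ds); m <- n_markers(ds)
    al <- matrix("0", nrow = n, ncol = 2L * m)
    g <- ds$genotypes
    for (j in seq_len(m)) {
      c1 <- ifelse(is.na(g[, j]), "0", ifelse(g[, j] >= 1L, mk$a1[j], mk$a2[j]))
      c2 <- ifelse(is.na(g[, j]), "0", ifelse(g[, j] == 2L, mk$a1[j], mk$a2[j]))
      al[, 2L * j - 1L] <- c1; al[, 2L * j] <- c2
    }
    ped <- cbind(ds$samples$group, ds$samples$sample_id, "0", "0", "0", "-9", al)
    utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                       sep = " ", row.names = FALSE, col.names = FALSE)
  } else {
    bim <- data.frame(mk$chromosome, mk$marker_id, 0L, mk$position, mk$a1, mk$a2)
    utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    fam <- data.frame(ds$samples$group, ds$samples$sample_id, 0L, 0L, 0L, -9L)
    utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    n <- n_samples(ds); m <- n_markers(ds); bpm <- ceiling(n / 4)
    # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
    code <- matrix(1L, nrow = 4L * bpm, ncol = m)       # padding reads as NA
    gc_ <- ds$genotypes
    cmap <- c(`0` = 3L, `1` = 2L, `2` = 0L)
    codes <- matrix(cmap[as.character(gc_)], nrow = n)
    codes[is.na(codes)] <- 1L
    code[seq_len(n), ] <- codes
    b1 <- as.integer(bitwAnd(code, 1L))
    b2 <- as.integer(bitwAnd(code, 2L) > 0)
    bits <- matrix(0L, nrow = 8, ncol = bpm * m)
    bits[seq(1, 8, by = 2), ] <- matrix(b1, nrow = 4)
    bits[seq(2, 8, by = 2), ] <- matrix(b2, nrow = 4)
    payload <- packBits(as.integer(bits) > 0, type = "raw")
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(payload, con)
  }
  invisible(prefix)
}
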