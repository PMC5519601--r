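#' Read a PLINK1 binary genotype fileset
#'
#' Decodes a SNP-major `.bed`/`.bim`/`.fam` triplet (magic bytes
#' `0x6c 0x1b 0x01`) into a [genotype matrix][simulate_genotypes].  Dosages
#' count the A1 allele: 2-bit code `00` = homozygous A1 (dosage 2),
#' `10` = heterozygous (1), `11` = homozygous A2 (0), `01` = missing.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return A `"genotype_matrix"` with sample order from the `.fam` file and
#'   variant order from the `.bim` file; `freqs` holds sample-estimated A1
#'   frequencies.
#' @examples
#' g <- simulate_genotypes(5, 8, seed = 1)
#' pre <- file.path(tempdir(), "toy")
#' write_plink(g, pre)
#' g2 <- read_plink(pre)
#' identical(g$dosage, g2$dosage)
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing PLINK files: ",
                            paste(missing, collapse = ", "))
  fam <- utils::read.table(paths[3], header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paths[2], header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  samples <- as.character(fam[[2]])
  if (anyDuplicated(samples)) stop("duplicate sample IDs in ", paths[3])
  if (anyDuplicated(bim$id)) stop("duplicate variant IDs in ", paths[2])
  n <- length(samples); m <- nrow(bim)
  bps <- (n + 3L) %/% 4L
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1])
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  if (length(body) != bps * m) {
    stop(".bed size inconsistent with .fam/.bim dimensions (expected ",
         bps * m, " data bytes, found ", length(body), ")")
  }
  # 2-bit decode via a 256 x 4 lookup (sample index grows from the low bits)
  code <- c(2L, NA_integer_, 1L, 0L)
  b <- 0:255
  lut <- cbind(code[bitwAnd(b, 3L) + 1L],
               code[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
               code[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
               code[bitwShiftR(b, 6L) + 1L])
  dec <- t(lut[as.integer(body) + 1L, , drop = FALSE])  # 4 x (bps*m)
  dim(dec) <- c(4L * bps, m)
  dos <- dec[seq_len(n), , drop = FALSE]
  map <- bim[, c("chr", "id", "pos", "a1", "a2")]
  dimnames(dos) <- list(samples, map$id)
  structure(list(dosage = dos, map = map,
                 freqs = colMeans(dos, na.rm = TRUE) / 2),
            class = "genotype_matrix")
}

#' Write a PLINK1 binary genotype fileset
#'
#' Inverse of [read_plink()]: writes SNP-major `.bed` (v1.00 magic
#' `0x6c 0x1b 0x01`) plus `.bim`/`.fam` text files.
#'
#' @param G A `"genotype_matrix"`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosage
  n <- nrow(dos); m <- ncol(dos)
  fam <- data.frame(rownames(dos), rownames(dos), 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(G$map$chr, G$map$id, 0L, G$map$pos, G$map$a1, G$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  codes <- matrix(3L, nrow = n, ncol = m)
  codes[which(dos == 2L)] <- 0L
  codes[which(dos == 1L)] <- 2L
  codes[which(is.na(dos))] <- 1L
  bps <- (n + 3L) %/% 4L
  pad <- matrix(0L, nrow = 4L * bps - n, ncol = m)
  cm <- rbind(codes, pad)
  dim(cm) <- c(4L, bps * m)
  bytes <- cm[1L, ] + 4L * cm[2L, ] + 16L * cm[3L, ] + 64L * cm[4L, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read or write a GCTA-format binary genomic relationship matrix
#'
#' The GCTA dialect: `<prefix>.grm.bin` holds the lower triangle
#' (diagonal included) of the relationship matrix row-major as
#' little-endian float32; `<prefix>.grm.N.bin` holds the per-pair count of
#' SNPs used in the same order and type; `<prefix>.grm.id` is a two-column
#' (family ID, individual ID) text file.
#'
#' @param grm A `"grm"` object (see [compute_grm()]).
#' @param prefix Path prefix.
#' @return `read_grm()` returns a `"grm"` object.
#' @examples
#' g <- simulate_genotypes(6, 40, seed = 1)
#' A <- compute_grm(g)
#' pre <- file.path(tempdir(), "toyg")
#' write_grm(A, pre)
#' A2 <- read_grm(pre)
#' max(abs(A$values - A2$values)) < 1e-6
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$samples)
  lt <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  ord <- order(lt[, 1L], lt[, 2L])
  lt <- lt[ord, , drop = FALSE]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(grm$values[lt]), con, size = 4L, endian = "little")
  close(con)
  nmat <- grm$n_snps
  if (is.null(dim(nmat))) nmat <- matrix(nmat, n, n)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(nmat[lt]), con, size = 4L, endian = "little")
  close(con)
  utils::write.table(data.frame(grm$samples, grm$samples),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE)
  samples <- as.character(ids[[2]])
  n <- length(samples)
  npair <- n * (n + 1L) / 2L
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = npair + 1L,
                  size = 4L, endian = "little")
  if (length(vals) != npair) {
    stop(".grm.bin size inconsistent with .grm.id (expected ", npair,
         " values, found ", length(vals), ")")
  }
  cnt <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = npair,
                 size = 4L, endian = "little")
  A <- matrix(0, n, n, dimnames = list(samples, samples))
  Nm <- A
  lt <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  ord <- order(lt[, 1L], lt[, 2L])
  lt <- lt[ord, , drop = FALSE]
  A[lt] <- vals; Nm[lt] <- cnt
  A[lt[, 2:1, drop = FALSE]] <- vals
  Nm[lt[, 2:1, drop = FALSE]] <- cnt
  structure(list(values = A, samples = samples, n_snps = Nm), class = "grm")
}
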