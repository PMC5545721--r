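#' Construct a genotype matrix object
#'
#' Container for minor-allele dosages (samples x SNPs, values 0/1/2 or NA)
#' plus per-SNP metadata.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids); entries in \{0, 1, 2, NA\}.
#' @param meta data.frame with one row per SNP: columns `id`, and optionally
#'   `chrom`, `pos`, `minor`, `major`, `maf`. Row order must match the
#'   dosage columns (matched by `id`).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, meta = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage)))
    stop2("dosage matrix needs SNP ids as colnames")
  if (is.null(rownames(dosage)))
    stop2("dosage matrix needs sample ids as rownames")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(dosage)), arr.ind = TRUE)[1, ]
    stop2(sprintf("invalid dosage %s at sample '%s', SNP '%s' (must be 0/1/2/NA)",
                  format(dosage[idx[1], idx[2]]),
                  rownames(dosage)[idx[1]], colnames(dosage)[idx[2]]))
  }
  if (is.null(meta)) {
    meta <- data.frame(id = colnames(dosage), stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta)
    if (!"id" %in% names(meta)) stop2("SNP metadata needs an 'id' column")
    if (!setequal(meta$id, colnames(dosage)))
      stop2("SNP metadata ids do not match dosage columns")
    meta <- meta[match(colnames(dosage), meta$id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(dosage = dosage, meta = meta), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Empirical minor allele frequencies from dosages
#'
#' @param geno a [geno_matrix].
#' @return named numeric vector of per-SNP empirical MAFs.
#' @export
empirical_maf <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

# normalize chromosome naming ("chr1" -> "1"); logs once when any change made
normalize_chrom <- function(chrom) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  if (!identical(out, as.character(chrom)))
    log_note("chrom_names_normalized", n = sum(out != as.character(chrom)))
  out
}

#' Candidate SNPs within windows around genes
#'
#' Retains SNPs whose position falls inside a closed interval
#' `[start - window_bp, end + window_bp]` around at least one gene, on the
#' gene's chromosome (the +/- 100 kb convention for assigning SNPs to a gene
#' set). Chromosome names are normalized across the "chr1" / "1" conventions.
#'
#' @param snp_meta data.frame with columns `id`, `chrom`, `pos` (1-based).
#' @param gene_coords data.frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based closed intervals).
#' @param window_bp window half-width in base pairs (default 100000).
#' @return list with `snp_ids` (retained SNP ids, input order) and `map`
#'   (data.frame SNP id -> overlapping gene).
#' @export
snps_in_gene_windows <- function(snp_meta, gene_coords, window_bp = 100000) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(snp_meta)),
            all(c("gene", "chrom", "start", "end") %in% names(gene_coords)),
            window_bp >= 0)
  sc <- normalize_chrom(snp_meta$chrom)
  gc <- normalize_chrom(gene_coords$chrom)
  maps <- list()
  for (ch in unique(gc)) {
    gi <- which(gc == ch)
    si <- which(sc == ch)
    if (!length(si)) next
    windows <- IRanges::IRanges(
      start = pmax(1L, gene_coords$start[gi] - window_bp),
      end = gene_coords$end[gi] + window_bp)
    snps <- IRanges::IRanges(start = snp_meta$pos[si], width = 1L)
    hits <- IRanges::findOverlaps(snps, windows)
    if (length(hits))
      maps[[ch]] <- data.frame(
        snp = snp_meta$id[si][S4Vectors::queryHits(hits)],
        gene = gene_coords$gene[gi][S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE)
  }
  map <- if (length(maps)) do.call(rbind, maps) else
    data.frame(snp = character(), gene = character())
  rownames(map) <- NULL
  keep <- snp_meta$id[snp_meta$id %in% map$snp]
  list(snp_ids = keep, map = map)
}
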