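#' Write a cohort to a VCF v4.2 file (GT-only FORMAT)
#'
#' Dosages 0/1/2 are written as unphased genotypes `0/0`, `0/1`, `1/1`;
#' missing dosages as `./.`.
#'
#' @param cohort A `pqtl_cohort` (or any list with `dosages`, `variants`,
#'   `samples`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  v <- cohort$variants
  d <- cohort$dosages
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$id), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    gts <- ifelse(is.na(d[, i]), "./.", gt_code[d[, i] + 1L])
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", ".",
            ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a GT-only VCF into a cohort-like object
#'
#' Parses a VCF v4.2 file with diploid GT fields into a dosage matrix.
#' Malformed lines raise an error naming the offending line number.
#'
#' @param path VCF file path.
#' @return A `pqtl_cohort` with `dosages`, `variants` and minimal
#'   `samples` (ids only); no kinship.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1) abort("malformed VCF: no #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) abort(sprintf("malformed VCF at line %d: fewer than 10 header columns", hdr_i))
  sample_ids <- hdr[-(1:9)]
  body_idx <- seq(hdr_i + 1L, length(lines))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  n <- length(sample_ids)
  m <- length(body_idx)
  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  variants <- vector("list", m)
  gt_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
              "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)
  for (k in seq_len(m)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 + n) {
      abort(sprintf("malformed VCF at line %d: expected %d fields, found %d",
                    ln, 9 + n, length(f)))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) abort(sprintf("malformed VCF at line %d: non-numeric POS", ln))
    gt <- sub(":.*", "", f[-(1:9)])
    codes <- gt_map[gt]
    if (any(is.na(codes) & !gt %in% c("./.", ".|.", "."))) {
      bad <- which(is.na(codes) & !gt %in% c("./.", ".|.", "."))[1]
      abort(sprintf("malformed VCF at line %d: unparseable GT '%s'", ln, gt[bad]))
    }
    dos[, k] <- unname(codes)
    variants[[k]] <- tibble::tibble(chrom = f[1], pos = pos, id = f[3],
                                    ref = f[4], alt = f[5])
  }
  variants <- dplyr::bind_rows(variants)
  rownames(dos) <- sample_ids
  colnames(dos) <- variants$id
  structure(list(dosages = dos, variants = variants,
                 samples = tibble::tibble(id = sample_ids),
                 kinship_truth = NULL, ref_freq = NULL),
            class = "pqtl_cohort")
}
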