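#' Read and write pipeline tables as TSV
#'
#' Thin wrappers with the fixed column orders used across the pipeline:
#' association tables (chrom, pos, id, ea, oa, maf, mac, miss, beta,
#' se, p), annotation tables, covariate tables and GRM matrices (TSV
#' with a sample-id header).
#'
#' @param x Object to write.
#' @param path File path.
#' @return The input (write) or the parsed object (read), invisibly for
#'   writers.
#' @name pqtl_io
NULL

#' @rdname pqtl_io
#' @export
write_assoc_tsv <- function(x, path) {
  cols <- c("chrom", "pos", "id", "ea", "oa", "maf", "mac", "miss",
            "beta", "se", "p")
  readr::write_tsv(dplyr::select(x, dplyr::all_of(cols)), path)
  invisible(x)
}

#' @rdname pqtl_io
#' @export
read_assoc_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = "c", id = "c",
                                                 ea = "c", oa = "c"))
  class(out) <- c("pqtl_assoc", class(out))
  out
}

#' @rdname pqtl_io
#' @export
write_annotation_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname pqtl_io
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", id = "c",
                                          consequence = "c",
                                          gene_links = "c")) |>
    dplyr::mutate(gene_links = dplyr::coalesce(gene_links, ""))
}

#' @rdname pqtl_io
#' @export
write_grm_tsv <- function(x, path) {
  K <- if (inherits(x, "pqtl_grm")) x$matrix else x
  df <- tibble::as_tibble(K, .name_repair = "minimal")
  names(df) <- colnames(K)
  readr::write_tsv(df, path)
  invisible(x)
}

#' @rdname pqtl_io
#' @export
read_grm_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  K <- as.matrix(df)
  rownames(K) <- colnames(K)
  structure(list(matrix = K, n_variants_used = NA_integer_,
                 sample_id = colnames(K)), class = "pqtl_grm")
}

#' Read or write a simulation configuration
#'
#' Simulation settings (counts, drift, effect sizes) as a flat
#' YAML-style key-value file, so a run can be reproduced from its
#' manifest.
#'
#' @param config Named list of scalar settings.
#' @param path File path.
#' @return The config list.
#' @export
write_sim_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s: %s", k, format(config[[k]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(config)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, function(x) trimws(x[1]), character(1))
  out
}
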