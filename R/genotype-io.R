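#' Read a dominant marker matrix
#'
#' Tab-delimited layout: header row of marker ids, first column the line id,
#' remaining cells 0 (tag absent) or 1 (tag present).  The loader is strict:
#' non-binary cells and duplicated line or marker ids are format errors.
#' Missing cells are rejected unless `impute = TRUE`, in which case they are
#' imputed to the marker mean rounded to 0/1 with a warning.
#'
#' @param path file path.
#' @param impute impute missing cells to the marker-wise majority allele.
#' @return binary matrix, rows = lines, columns = markers.
#' @export
read_markers <- function(path, impute = FALSE) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_config("malformed genotype file: %s", path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop_config("duplicate line id(s): %s",
                                      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mk <- colnames(tab)[-1L]
  if (anyDuplicated(mk)) stop_config("duplicate marker id(s): %s",
                                     paste(unique(mk[duplicated(mk)]), collapse = ", "))
  M <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  if (anyNA(M)) {
    if (!impute) {
      bad <- which(is.na(M), arr.ind = TRUE)[1L, ]
      stop_config("missing genotype at line '%s', marker '%s' (set impute=TRUE to fill)",
                  ids[bad[1L]], mk[bad[2L]])
    }
    n_miss <- sum(is.na(M))
    for (j in which(colSums(is.na(M)) > 0L)) {
      M[is.na(M[, j]), j] <- round(mean(M[, j], na.rm = TRUE))
    }
    warning(sprintf("imputed %d missing genotype cell(s) to the marker majority allele", n_miss))
  }
  bad <- which(!(M %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(M))
    stop_config("non-binary genotype value '%s' at line '%s', marker '%s'",
                format(M[bad[1L]]), ids[rc[1L]], mk[rc[2L]])
  }
  storage.mode(M) <- "integer"
  M
}

#' @rdname read_markers
#' @param markers binary lines x markers matrix with dimnames.
#' @export
write_markers <- function(markers, path) {
  stopifnot(is.matrix(markers), !is.null(rownames(markers)),
            !is.null(colnames(markers)))
  df <- data.frame(line_id = rownames(markers), markers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pedigree and phenotype table I/O
#'
#' Tab-delimited tables: pedigree columns (`line_id`, `parent1`, `parent2`,
#' `year`, `tester`); phenotype columns (`line_id`, `year`, `location`,
#' `rep`, `block`, `value`).
#'
#' @param x data frame to write.
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "parent1", "parent2", "year")
  if (!all(need %in% names(ped)))
    stop_config("pedigree file must have columns %s", paste(need, collapse = ", "))
  ped
}

#' @rdname table_io
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "year", "location", "rep", "value")
  if (!all(need %in% names(ph)))
    stop_config("phenotype file must have columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(ph$value))) stop_config("non-finite phenotype value(s)")
  ph
}

#' Minor-allele-frequency filter for dominant markers
#'
#' For a presence/absence tag the allele frequency is the fraction `f` of
#' lines carrying the tag and MAF = min(f, 1 - f).  Markers with MAF
#' strictly below `threshold` are discarded (a marker at exactly the
#' threshold is kept); column order of retained markers is preserved.
#'
#' @param markers binary lines x markers matrix.
#' @param threshold MAF cutoff in \[0, 0.5\]; default 0.05.
#' @return filtered matrix with attribute `filter_report`
#'   (list: `n_in`, `n_kept`, `n_removed`, `threshold`).
#' @export
maf_filter <- function(markers, threshold = 0.05) {
  if (!is.matrix(markers) || nrow(markers) < 1L || ncol(markers) < 1L)
    stop_config("markers must be a non-empty matrix")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 0.5)
    stop_config("threshold must lie in [0, 0.5]")
  f <- colMeans(markers)
  maf <- pmin(f, 1 - f)
  keep <- maf >= threshold
  out <- markers[, keep, drop = FALSE]
  map <- attr(markers, "map")
  if (!is.null(map)) attr(out, "map") <- map[map$marker %in% colnames(out), ]
  attr(out, "filter_report") <- list(n_in = ncol(markers), n_kept = sum(keep),
                                     n_removed = sum(!keep), threshold = threshold)
  out
}

#' Centre and standardize a marker matrix
#'
#' Each marker column is centred to mean zero and scaled to unit sample
#' standard deviation (denominator n - 1), which makes the genomic
#' relationship matrix built from it satisfy trace(G) = n - 1.
#'
#' @param markers binary (or numeric) lines x markers matrix.
#' @return numeric matrix Z of the same shape.
#' @export
standardize_markers <- function(markers) {
  if (nrow(markers) < 2L) stop_config("need at least 2 lines to standardize")
  s <- apply(markers, 2, stats::sd)
  if (any(s < 1e-12)) {
    bad <- colnames(markers)[which(s < 1e-12)[1L]]
    stop_config("marker '%s' has zero variance; run maf_filter() first", bad)
  }
  Z <- scale(markers, center = TRUE, scale = s)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  Z
}

#' Genomic relationship matrix from standardized markers
#'
#' G = Z Z' / p where Z is the centred, standardized marker matrix and p
#' the number of markers.  With sample-sd standardization trace(G) = n - 1.
#'
#' @param Z standardized marker matrix from [standardize_markers()], or a
#'   raw binary matrix (standardized internally).
#' @return object of class `genomic_relationship`: `G` (symmetric n x n),
#'   `p` (marker count), `line_ids`.
#' @export
grm <- function(Z) {
  if (!is.matrix(Z) || ncol(Z) < 1L) stop_config("Z must have at least one marker")
  already_std <- max(abs(colMeans(Z))) < 1e-8 &&
    max(abs(apply(Z, 2, stats::sd) - 1)) < 1e-6
  if (!already_std) Z <- standardize_markers(Z)
  G <- tcrossprod(Z) / ncol(Z)
  G <- (G + t(G)) / 2
  structure(list(G = G, p = ncol(Z), line_ids = rownames(Z)),
            class = "genomic_relationship")
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat("genomic_relationship:", nrow(x$G), "lines,", x$p, "markers; trace =",
      format(sum(diag(x$G)), digits = 6), "\n")
  invisible(x)
}

as_grm_matrix <- function(G) {
  if (inherits(G, "genomic_relationship")) G$G else G
}

#' @rdname grm
#' @param G a `genomic_relationship` object.
#' @param path file path for the tab-delimited square matrix.
#' @export
write_grm <- function(G, path) {
  M <- as_grm_matrix(G)
  df <- data.frame(line_id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grm
#' @export
read_grm <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  M <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(M) <- as.character(tab[[1L]])
  structure(list(G = M, p = NA_integer_, line_ids = rownames(M)),
            class = "genomic_relationship")
}
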