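#' Construct a genotype matrix object
#'
#' A `genotype_matrix` is an integer matrix of allele-A dosages with
#' individuals in rows and biallelic markers in columns. Non-missing entries
#' must be 0, 1 or 2 (copies of the reference allele A); missing genotypes
#' are `NA`.
#'
#' @param codes numeric/integer matrix (n individuals x m markers) with
#'   entries in `{0, 1, 2, NA}`.
#' @param ids character vector of unique individual identifiers; defaults to
#'   `rownames(codes)`.
#' @param markers character vector of unique marker identifiers; defaults to
#'   `colnames(codes)`.
#' @return an object of class `genotype_matrix` (an integer matrix with
#'   `ids` as row names and `markers` as column names).
#' @examples
#' g <- genotype_matrix(rbind(c(2, 1), c(0, 1)),
#'                      ids = c("a", "b"), markers = c("m1", "m2"))
#' @export
genotype_matrix <- function(codes, ids = rownames(codes),
                            markers = colnames(codes)) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  m <- ncol(codes)
  if (n < 1L || m < 1L) {
    stop("genotype matrix must have at least one individual and one marker")
  }
  if (is.null(ids)) ids <- paste0("ind_", seq_len(n))
  if (is.null(markers)) markers <- paste0("mk_", seq_len(m))
  ids <- as.character(ids)
  markers <- as.character(markers)
  if (length(ids) != n) stop("length of 'ids' does not match nrow(codes)")
  if (length(markers) != m) stop("length of 'markers' does not match ncol(codes)")
  if (anyDuplicated(ids)) {
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(markers)) {
    stop("duplicate marker ids: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid genotype code %s for individual '%s' at marker '%s' (must be 0, 1, 2 or missing)",
      format(codes[idx[1L], idx[2L]]), ids[idx[1L]], markers[idx[2L]]))
  }
  storage.mode(codes) <- "integer"
  dimnames(codes) <- list(ids, markers)
  class(codes) <- c("genotype_matrix", class(codes))
  codes
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers, %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a genotype matrix from disk
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`matrix012`}{tab-separated; header row names the markers (a
#'     leading `id` header token for the first column is allowed), first
#'     column holds individual ids, cells in `{0, 1, 2}` or the missing
#'     token.}
#'   \item{`plink_raw`}{whitespace-separated PLINK `--recode A` dialect with
#'     columns `FID IID PAT MAT SEX PHENOTYPE` followed by one allele-dosage
#'     column per marker; only `IID` and the marker columns are used.}
#' }
#' Cells equal to the declared missing token become missing; any other
#' unparseable cell is an error naming the offending individual and marker.
#'
#' @param path path to the genotype file.
#' @param format `"matrix012"` or `"plink_raw"`.
#' @param missing missing-value token, default `"NA"` (PLINK also uses
#'   `"-9"` in some exports).
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("matrix012", "plink_raw"),
                           missing = "NA") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  sep <- if (format == "matrix012") "\t" else "auto"
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          na.strings = NULL, sep = sep, data.table = FALSE)
  if (format == "matrix012") {
    ids <- dt[[1L]]
    markers <- colnames(dt)[-1L]
    cells <- as.matrix(dt[, -1L, drop = FALSE])
  } else {
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!("IID" %in% colnames(dt))) {
      stop("plink_raw file lacks an IID column: ", path)
    }
    ids <- dt[["IID"]]
    markers <- setdiff(colnames(dt), meta)
    if (length(markers) == 0L) stop("plink_raw file has no marker columns")
    cells <- as.matrix(dt[, markers, drop = FALSE])
  }
  codes <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  is_missing <- cells == missing
  bad <- (!is_missing) & (is.na(codes) | !(codes %in% c(0, 1, 2)))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "unparseable genotype '%s' for individual '%s' at marker '%s' (expected 0/1/2 or '%s')",
      cells[idx[1L], idx[2L]], ids[idx[1L]], markers[idx[2L]], missing))
  }
  codes[is_missing] <- NA
  genotype_matrix(codes, ids = ids, markers = markers)
}

#' Write a genotype matrix in the matrix012 dialect
#'
#' @param g a [genotype_matrix].
#' @param path output path (tab-separated, `id` header for the first column).
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(id = rownames(g), as.data.frame(unclass(g)),
                   check.names = FALSE)
  write_tsv_atomic(df, path)
}

#' Per-marker genotype and allele frequencies
#'
#' Frequencies are computed over non-missing individuals only
#' (pairwise-complete denominators). The allele-A frequency is
#' `p = pAA + pAa/2`.
#'
#' @param g a [genotype_matrix].
#' @return a data frame of class `genotype_freqs` with one row per marker and
#'   columns `marker`, `nAA`, `nAa`, `naa`, `n_obs`, `pAA`, `pAa`, `paa`,
#'   `p`, `q`.
#' @export
compute_frequencies <- function(g) {
  nAA <- colSums(g == 2L, na.rm = TRUE)
  nAa <- colSums(g == 1L, na.rm = TRUE)
  naa <- colSums(g == 0L, na.rm = TRUE)
  n_obs <- nAA + nAa + naa
  if (any(n_obs == 0L)) {
    stop("marker(s) with all genotypes missing: ",
         paste(colnames(g)[n_obs == 0L], collapse = ", "))
  }
  pAA <- nAA / n_obs
  pAa <- nAa / n_obs
  paa <- naa / n_obs
  p <- pAA + pAa / 2
  out <- data.frame(marker = colnames(g), nAA = as.integer(nAA),
                    nAa = as.integer(nAa), naa = as.integer(naa),
                    n_obs = as.integer(n_obs), pAA = pAA, pAa = pAa, paa = paa,
                    p = p, q = 1 - p, row.names = NULL,
                    stringsAsFactors = FALSE)
  stopifnot(all(abs(out$pAA + out$pAa + out$paa - 1) < 1e-12),
            all(out$p >= 0 & out$p <= 1))
  class(out) <- c("genotype_freqs", "data.frame")
  out
}

#' Heterozygote excess relative to Hardy-Weinberg expectation
#'
#' For each marker, `(pAa - 2pq) / (2pq)`; positive values indicate an
#' excess of heterozygotes (the signature of a cross between divergent
#' populations). Markers with `2pq = 0` carry no information about excess
#' and are flagged and excluded from the mean.
#'
#' @param f a `genotype_freqs` data frame (see [compute_frequencies()]), or
#'   any data frame with columns `pAa`, `p`, `q` (and optionally `marker`).
#' @return a list with `per_marker` (data frame: `marker`, `het_excess`,
#'   `included`), `mean_excess` (mean over included markers; `NA` if none)
#'   and `n_included`.
#' @export
heterozygote_excess <- function(f) {
  two_pq <- 2 * f$p * f$q
  included <- two_pq > 0
  he <- ifelse(included, (f$pAa - two_pq) / two_pq, NA_real_)
  per_marker <- data.frame(
    marker = f$marker %||% paste0("mk_", seq_along(he)),
    het_excess = he, included = included, stringsAsFactors = FALSE)
  list(per_marker = per_marker,
       mean_excess = if (any(included)) mean(he[included]) else NA_real_,
       n_included = sum(included))
}
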