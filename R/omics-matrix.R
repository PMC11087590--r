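#' Labeled omics matrix with per-sample metadata
#'
#' Container for a features x samples numeric matrix (counts, TPM, RPKM or a
#' log2(x+1) transform of one of those) together with the sample metadata the
#' downstream statistics need (tissue, time point, group, animal).
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row and
#'   column names are mandatory and must be unique.
#' @param unit One of `"count"`, `"TPM"`, `"RPKM"`, `"log2TPM1"`,
#'   `"log2RPKM1"`, `"log2CPM1"`. Unit changes only happen through the
#'   explicit transform functions, never by mutating this field.
#' @param meta data.frame with one row per sample; must contain a
#'   `sample_id` column covering every column of `values`. Conventional extra
#'   columns: `tissue`, `time_point`, `group`, `animal_id`.
#' @return An object of class `OmicsMatrix` (a list with elements `values`,
#'   `unit`, `meta`; `meta` rows are aligned to the columns of `values`).
#' @export
omics_matrix <- function(values, unit, meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  units_ok <- c("count", "TPM", "RPKM", "log2TPM1", "log2RPKM1", "log2CPM1")
  if (!unit %in% units_ok) {
    stop("unknown unit '", unit, "'; expected one of ",
         paste(units_ok, collapse = ", "))
  }
  if (is.null(rownames(values)) || is.null(colnames(values)) ||
      anyNA(rownames(values)) || anyNA(colnames(values)) ||
      any(rownames(values) == "") || any(colnames(values) == "")) {
    stop("values must have complete row (feature) and column (sample) names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0, na.rm = TRUE) && !startsWith(unit, "log2")) {
    stop("negative values are not allowed for unit '", unit, "'")
  }
  if (!is.data.frame(meta) || !"sample_id" %in% names(meta)) {
    stop("meta must be a data.frame with a sample_id column")
  }
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta)) {
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, unit = unit, meta = meta),
            class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  if ("tissue" %in% names(x$meta)) {
    cat("tissues:", paste(unique(x$meta$tissue), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an OmicsMatrix by samples and/or features
#'
#' @param om An `OmicsMatrix`.
#' @param samples,features Character vectors of ids to keep (default all).
#' @return A new `OmicsMatrix`.
#' @export
om_subset <- function(om, samples = colnames(om$values),
                      features = rownames(om$values)) {
  stopifnot(inherits(om, "OmicsMatrix"))
  omics_matrix(om$values[features, samples, drop = FALSE], om$unit,
               om$meta[om$meta$sample_id %in% samples, , drop = FALSE])
}

#' Counts-per-million normalization
#'
#' @param om An `OmicsMatrix` with `unit == "count"`.
#' @return An `OmicsMatrix` of log2(CPM+1) values (unit `"log2CPM1"`).
#' @export
om_log2cpm <- function(om) {
  stopifnot(inherits(om, "OmicsMatrix"), om$unit == "count")
  libsize <- colSums(om$values)
  if (any(libsize == 0)) stop("zero library size in sample(s): ",
                              paste(colnames(om$values)[libsize == 0],
                                    collapse = ", "))
  cpm <- sweep(om$values, 2, libsize, "/") * 1e6
  omics_matrix(log2(cpm + 1), "log2CPM1", om$meta)
}

#' log2(x+1) transform of a TPM or RPKM matrix
#'
#' @param om An `OmicsMatrix` with unit `"TPM"` or `"RPKM"`.
#' @return An `OmicsMatrix` with unit `"log2TPM1"` or `"log2RPKM1"`.
#' @export
om_log2p1 <- function(om) {
  stopifnot(inherits(om, "OmicsMatrix"))
  unit <- switch(om$unit, TPM = "log2TPM1", RPKM = "log2RPKM1",
                 stop("om_log2p1 expects unit TPM or RPKM, got ", om$unit))
  omics_matrix(log2(om$values + 1), unit, om$meta)
}

#' TPM from a count matrix and gene lengths
#'
#' Rate = count / length(kb); TPM scales rates so each sample sums to 1e6.
#'
#' @param om An `OmicsMatrix` of counts.
#' @param lengths_bp Named numeric vector of feature lengths in bp, covering
#'   all features of `om`.
#' @return An `OmicsMatrix` with unit `"TPM"`.
#' @export
om_tpm <- function(om, lengths_bp) {
  stopifnot(inherits(om, "OmicsMatrix"), om$unit == "count")
  lens <- lengths_bp[rownames(om$values)]
  if (anyNA(lens)) stop("lengths_bp missing for some features")
  rate <- om$values / (lens / 1000)
  denom <- colSums(rate)
  if (any(denom == 0)) stop("all-zero sample(s) cannot be TPM-normalized")
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  omics_matrix(tpm, "TPM", om$meta)
}
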