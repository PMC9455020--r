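#' Encode genotypes as a dosage matrix
#'
#' Counts of the variant allele: WW = 0, WV = 1, VV = 2.  Missing calls are an
#' error under the default policy, or replaced by the locus mean under
#' \code{impute = "mean"}.  A locus missing in every individual is always an
#' error.
#'
#' @param table a \code{genotype_table}.
#' @param impute \code{"error"} (default) or \code{"mean"}.
#' @return a numeric matrix, individuals x loci.
#' @export
encode_dosage <- function(table, impute = c("error", "mean")) {
  impute <- match.arg(impute)
  x <- table$calls
  storage.mode(x) <- "double"
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("locus with no typed individuals: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  if (anyNA(x)) {
    if (impute == "error")
      stop("missing calls present; use impute = \"mean\" or drop individuals")
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x
}

#' Principal component analysis of a dosage matrix
#'
#' Column-centred (optionally unit-scaled) PCA via singular value
#' decomposition.  Constant columns are dropped with a warning before the
#' decomposition.  Contribution ratios are the normalised eigenvalues
#' \eqn{\lambda_i / \sum \lambda}.  For reproducibility the sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param x numeric matrix, individuals x loci (see
#'   \code{\link{encode_dosage}}).
#' @param center,scale passed to the decomposition; the defaults (centre,
#'   no scaling) match the common default for genotype PCA.
#' @return a list of class \code{pca_result} with \code{scores},
#'   \code{loadings}, \code{sdev}, \code{contribution_ratios},
#'   \code{centered}, \code{scaled} and \code{encoding}.
#' @export
run_pca <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (nrow(unique(x)) < 2) stop("need at least 2 distinct rows")
  constant <- apply(x, 2, function(col) max(col) == min(col))
  if (any(constant)) {
    warning(sum(constant), " constant column(s) dropped before PCA: ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
    x <- x[, !constant, drop = FALSE]
  }
  if (!ncol(x)) stop("no non-constant columns left")
  pc <- stats::prcomp(x, center = center, scale. = scale)
  # deterministic sign: largest |loading| of each component is positive
  for (k in seq_len(ncol(pc$rotation))) {
    top <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[top, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  lambda <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
                 contribution_ratios = lambda / sum(lambda),
                 centered = center, scaled = scale,
                 encoding = "variant_allele_dosage"),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(4, length(x$contribution_ratios))
  cat("PCA of", nrow(x$scores), "individuals;",
      "contribution ratios (first", k, "):",
      paste0(sprintf("%.1f%%", 100 * x$contribution_ratios[1:k]), collapse = ", "),
      "\n")
  invisible(x)
}

#' PCA of a genotype table
#'
#' Convenience wrapper: dosage encoding (mean imputation for missing calls)
#' followed by \code{\link{run_pca}}.
#'
#' @inheritParams encode_dosage
#' @inheritParams run_pca
#' @return a \code{pca_result}.
#' @export
pca_genotypes <- function(table, center = TRUE, scale = FALSE) {
  run_pca(encode_dosage(table, impute = "mean"), center = center, scale = scale)
}
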