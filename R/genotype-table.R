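#' @keywords internal
"_PACKAGE"

# Canonical cell vocabulary of the genotype-table text dialect, mapped to
# variant-allele dosage (0 = WW, 1 = WV, 2 = VV).  The non-canonical tokens
# observed in published tables ("WD Heter", "W Heter", "W Hetero") are accepted
# as heterozygotes but counted and reported as normalisations.
.dialect_canonical <- c(
  "W Homo" = 0L, "D Homo" = 2L, "I Homo" = 2L,
  "WD Hetero" = 1L, "WI Hetero" = 1L
)
.dialect_variants <- c("WD Heter" = 1L, "WI Heter" = 1L, "W Heter" = 1L, "W Hetero" = 1L)
.missing_tokens <- c("", "-", "NA", "missing")

.metadata_cols <- c("sample_id", "region", "sex", "haplotype", "family_id", "relationship")

#' Read a marker panel definition
#'
#' Reads a tab-separated marker table with columns \code{marker_id},
#' \code{variant_type} (\code{"insertion"} or \code{"deletion"}),
#' \code{indel_size} and \code{product_bp} (PCR product length of the wild
#' allele), plus optional coordinate and primer columns carried as metadata.
#'
#' @param path path to a TSV file.
#' @return a data.frame of class \code{marker_panel}, one row per marker.
#' @export
read_marker_panel <- function(path) {
  m <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE)
  req <- c("marker_id", "variant_type", "indel_size", "product_bp")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("marker panel lacks column(s): ", paste(miss, collapse = ", "))
  m$indel_size <- as.integer(m$indel_size)
  m$product_bp <- as.integer(m$product_bp)
  if (anyDuplicated(m$marker_id)) stop("duplicate marker_id in panel")
  if (!all(m$variant_type %in% c("insertion", "deletion")))
    stop("variant_type must be 'insertion' or 'deletion'")
  if (any(m$indel_size <= 0)) stop("indel_size must be positive")
  if (any(m$product_bp <= m$indel_size))
    stop("amplicon must be longer than the InDel it spans")
  class(m) <- c("marker_panel", "data.frame")
  m
}

#' The bundled 11-marker red-crowned crane panel
#'
#' @return a \code{marker_panel} data.frame with 11 biallelic InDel markers
#'   (30-36 bp insertions/deletions resolvable on 3\% agarose gels).
#' @export
crane_marker_panel <- function() {
  read_marker_panel(system.file("extdata", "markers_panel.tsv",
                                package = "indelpop", mustWork = TRUE))
}

#' Parse a genotype table in the textual InDel dialect
#'
#' Reads a tab-separated table with one row per individual.  A \code{sample_id}
#' column is required; \code{region}, \code{sex}, \code{haplotype},
#' \code{family_id} and \code{relationship} are carried as metadata when
#' present.  Every remaining column is taken as a marker column whose cells are
#' drawn from the dialect vocabulary (\code{"W Homo"}, \code{"D Homo"},
#' \code{"I Homo"}, \code{"WD Hetero"}, \code{"WI Hetero"}).  The typographic
#' variants \code{"WD Heter"}, \code{"W Heter"} and \code{"W Hetero"} are
#' normalised to heterozygote calls; each such cell is recorded in the
#' \code{normalizations} component and reported via a single consolidated
#' warning.  Unknown tokens are an error naming the offending row and column.
#'
#' @param path path to a TSV file (or a character vector of lines via
#'   \code{text}).
#' @param text optional character scalar holding the file contents; overrides
#'   \code{path}.
#' @param markers optional \code{marker_panel}; when given, marker columns are
#'   matched (and ordered) by panel \code{marker_id} and allele letters are
#'   checked against each marker's variant type.
#' @param quiet suppress the normalisation warning.
#' @return an object of class \code{genotype_table}: a list with components
#'   \code{calls} (integer matrix, individuals x markers, variant-allele dosage
#'   0/1/2 with \code{NA} for missing), \code{samples} (metadata data.frame),
#'   \code{markers} (marker panel or minimal id table) and
#'   \code{normalizations} (data.frame of normalised cells).
#' @export
parse_genotype_table <- function(path = NULL, text = NULL, markers = NULL,
                                 quiet = FALSE) {
  d <- if (!is.null(text)) {
    utils::read.delim(textConnection(text), check.names = FALSE,
                      colClasses = "character", stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, check.names = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(d)) stop("genotype table needs a 'sample_id' column")
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))

  marker_cols <- setdiff(names(d), .metadata_cols)
  if (!is.null(markers)) {
    unknown <- setdiff(marker_cols, markers$marker_id)
    if (length(unknown)) stop("columns not in marker panel: ", paste(unknown, collapse = ", "))
    marker_cols <- intersect(markers$marker_id, marker_cols)
  }
  if (!length(marker_cols)) stop("no marker columns found")

  vocab <- c(.dialect_canonical, .dialect_variants)
  calls <- matrix(NA_integer_, nrow(d), length(marker_cols),
                  dimnames = list(d$sample_id, marker_cols))
  norm <- list()
  for (j in seq_along(marker_cols)) {
    cell <- trimws(d[[marker_cols[j]]])
    known <- cell %in% names(vocab) | cell %in% .missing_tokens
    if (!all(known)) {
      i <- which(!known)[1]
      stop(sprintf("unknown genotype token '%s' at row %d (sample %s), column %s",
                   cell[i], i, d$sample_id[i], marker_cols[j]))
    }
    dos <- rep(NA_integer_, length(cell))
    in_vocab <- cell %in% names(vocab)
    dos[in_vocab] <- vocab[cell[in_vocab]]
    calls[, j] <- dos
    noncan <- which(cell %in% names(.dialect_variants))
    if (length(noncan)) {
      norm[[length(norm) + 1L]] <- data.frame(
        sample_id = d$sample_id[noncan], marker_id = marker_cols[j],
        token = cell[noncan], normalized_to = "heterozygote",
        stringsAsFactors = FALSE)
    }
    # each locus is strictly biallelic: a column never mixes I and D alleles
    both <- any(grepl("I", cell[in_vocab], fixed = TRUE)) &&
      any(grepl("D", cell[in_vocab], fixed = TRUE))
    if (both)
      stop("column ", marker_cols[j],
           " mixes insertion and deletion alleles; loci are strictly biallelic")
    if (!is.null(markers)) {
      vt <- markers$variant_type[markers$marker_id == marker_cols[j]]
      bad <- if (vt == "insertion") any(grepl("D", cell[in_vocab], fixed = TRUE))
             else any(grepl("I", cell[in_vocab], fixed = TRUE))
      if (bad) stop("column ", marker_cols[j], " uses alleles inconsistent with its ",
                    vt, " marker definition")
    }
  }
  norm <- if (length(norm)) do.call(rbind, norm) else
    data.frame(sample_id = character(), marker_id = character(),
               token = character(), normalized_to = character(),
               stringsAsFactors = FALSE)
  if (nrow(norm) && !quiet)
    warning(nrow(norm), " non-canonical genotype token(s) normalised to heterozygote calls",
            call. = FALSE)

  samples <- d[intersect(.metadata_cols, names(d))]
  for (f in c("sex", "haplotype", "region"))
    if (f %in% names(samples))
      samples[[f]][samples[[f]] %in% .missing_tokens] <- "unknown"
  mk <- if (!is.null(markers)) markers[match(marker_cols, markers$marker_id), ]
        else data.frame(marker_id = marker_cols, stringsAsFactors = FALSE)
  structure(list(calls = calls, samples = samples, markers = mk,
                 normalizations = norm),
            class = "genotype_table")
}

#' Build a genotype table from a dosage matrix
#'
#' Programmatic constructor used by the simulator and by tests.
#'
#' @param calls integer matrix (individuals x markers) of variant-allele
#'   dosages 0/1/2, \code{NA} for missing; dimnames supply ids.
#' @param samples optional metadata data.frame with a \code{sample_id} column.
#' @param markers optional marker panel.
#' @return a \code{genotype_table}.
#' @export
genotype_table <- function(calls, samples = NULL, markers = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) rownames(calls) <- as.character(seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("L%02d", seq_len(ncol(calls)))
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(samples))
    samples <- data.frame(sample_id = rownames(calls), stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (nrow(samples) != nrow(calls)) stop("metadata rows do not match call matrix")
  if (is.null(markers))
    markers <- data.frame(marker_id = colnames(calls), stringsAsFactors = FALSE)
  structure(list(calls = calls, samples = samples, markers = markers,
                 normalizations = data.frame(sample_id = character(),
                                             marker_id = character(),
                                             token = character(),
                                             normalized_to = character(),
                                             stringsAsFactors = FALSE)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$calls), "individuals x", ncol(x$calls), "markers\n")
  if (nrow(x$normalizations))
    cat("  (", nrow(x$normalizations), "normalised non-canonical cells )\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Subset a genotype table by individuals
#'
#' @param x a \code{genotype_table}.
#' @param ids sample ids (or logical/integer index) to keep.
#' @return the subsetted \code{genotype_table}.
#' @export
subset_individuals <- function(x, ids) {
  idx <- if (is.character(ids)) match(ids, x$samples$sample_id) else ids
  if (is.character(ids) && anyNA(idx))
    stop("unknown sample id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  structure(list(calls = x$calls[idx, , drop = FALSE],
                 samples = x$samples[idx, , drop = FALSE],
                 markers = x$markers,
                 normalizations = x$normalizations),
            class = "genotype_table")
}

#' Serialise a genotype table back to the text dialect
#'
#' The inverse of \code{\link{parse_genotype_table}}.  Dosages are written with
#' the canonical vocabulary; the allele letter for homozygous/heterozygous
#' variant calls is taken from each marker's \code{variant_type} (defaulting to
#' deletion when the panel carries no type).  An optional \code{typo_rate}
#' rewrites heterozygote tokens with the non-canonical variants seen in the
#' published tables, to exercise parser normalisation.
#'
#' @param x a \code{genotype_table}.
#' @param path optional file to write; when \code{NULL} the TSV text is
#'   returned invisibly as a character scalar.
#' @param typo_rate probability that a heterozygote cell is written with a
#'   truncated token ("WD Heter"); requires \code{seed} for reproducibility.
#' @param seed integer seed used when \code{typo_rate > 0}.
#' @return the TSV text, invisibly.
#' @export
write_genotype_table <- function(x, path = NULL, typo_rate = 0, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"), typo_rate >= 0, typo_rate < 1)
  vt <- if ("variant_type" %in% names(x$markers)) x$markers$variant_type
        else rep("deletion", ncol(x$calls))
  lett <- ifelse(vt == "insertion", "I", "D")
  tok <- matrix("", nrow(x$calls), ncol(x$calls))
  for (j in seq_len(ncol(x$calls))) {
    tok[, j] <- c("W Homo", paste0("W", lett[j], " Hetero"), paste0(lett[j], " Homo")
                  )[x$calls[, j] + 1L]
    tok[is.na(x$calls[, j]), j] <- "-"
  }
  if (typo_rate > 0) {
    if (is.null(seed)) stop("typo_rate > 0 needs a seed")
    het <- which(!is.na(x$calls) & x$calls == 1L)
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    hit <- het[stats::runif(length(het)) < typo_rate]
    tok[hit] <- sub(" Hetero$", " Heter", tok[hit])
  }
  colnames(tok) <- colnames(x$calls)
  out <- cbind(x$samples, as.data.frame(tok, stringsAsFactors = FALSE,
                                        check.names = FALSE))
  txt <- paste(c(paste(names(out), collapse = "\t"),
                 apply(out, 1, paste, collapse = "\t")), collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Bundled crane genotype tables and study sample sets
#'
#' \code{crane_nonkin_table} loads the 39 non-kin individuals (13 each from the
#' Kushiro, Nemuro and Tokachi regions of eastern Hokkaido);
#' \code{crane_kin_table} loads the 39 individuals of the 12 known families.
#' \code{select_dataset} returns either table or their union, in which the 12
#' individuals present in both are deduplicated by sample id (the non-kin copy
#' is kept), giving 66 unique cranes.
#'
#' @return a \code{genotype_table}.
#' @export
crane_nonkin_table <- function() {
  parse_genotype_table(system.file("extdata", "genotypes_nonkin.tsv",
                                   package = "indelpop", mustWork = TRUE),
                       markers = crane_marker_panel(), quiet = TRUE)
}

#' @rdname crane_nonkin_table
#' @export
crane_kin_table <- function() {
  parse_genotype_table(system.file("extdata", "genotypes_kin.tsv",
                                   package = "indelpop", mustWork = TRUE),
                       markers = crane_marker_panel(), quiet = TRUE)
}

#' @rdname crane_nonkin_table
#' @param which one of \code{"non_kin"}, \code{"kin"}, \code{"union"}.
#' @export
select_dataset <- function(which = c("non_kin", "kin", "union")) {
  which <- match.arg(which)
  switch(which,
         non_kin = crane_nonkin_table(),
         kin = crane_kin_table(),
         union = union_tables(crane_nonkin_table(), crane_kin_table()))
}

#' Union of two genotype tables, deduplicated by sample id
#'
#' Rows of \code{y} whose \code{sample_id} already occurs in \code{x} are
#' dropped; marker columns must agree.
#'
#' @param x,y \code{genotype_table}s over the same marker panel.
#' @return a \code{genotype_table}.
#' @export
union_tables <- function(x, y) {
  if (!identical(colnames(x$calls), colnames(y$calls)))
    stop("tables are typed on different marker panels")
  keep <- !(y$samples$sample_id %in% x$samples$sample_id)
  common <- intersect(names(x$samples), names(y$samples))
  samples <- rbind(x$samples[common], y$samples[keep, common, drop = FALSE])
  rownames(samples) <- NULL
  structure(list(calls = rbind(x$calls, y$calls[keep, , drop = FALSE]),
                 samples = samples, markers = x$markers,
                 normalizations = rbind(x$normalizations, y$normalizations[
                   y$normalizations$sample_id %in% y$samples$sample_id[keep] |
                     !(y$normalizations$sample_id %in% x$samples$sample_id), ])),
            class = "genotype_table")
}

#' Predict agarose gel band lengths for a genotype call
#'
#' The wild (W) allele amplifies at the marker's wild-allele product length;
#' the variant allele at that length minus the InDel size for deletions and
#' plus it for insertions.  Heterozygotes may additionally show a slower
#' heteroduplex band (mismatched-strand annealing), flagged but not assigned a
#' length.  Because the published product length for the one insertion marker
#' could refer to either allele, \code{product_refers_to} switches the
#' convention.
#'
#' @param marker a one-row data.frame (or list) with \code{variant_type},
#'   \code{indel_size} and \code{product_bp}.
#' @param call dosage 0 (WW), 1 (WV) or 2 (VV); missing is an error.
#' @param product_refers_to whether \code{product_bp} is the product of the
#'   wild allele (default) or of the variant allele.
#' @return a list with \code{fragment_lengths} (sorted bp) and
#'   \code{heteroduplex_possible}.
#' @export
predict_band_pattern <- function(marker, call,
                                 product_refers_to = c("wild", "variant")) {
  product_refers_to <- match.arg(product_refers_to)
  if (is.na(call)) stop("cannot predict bands for a missing call")
  stopifnot(call %in% 0:2, marker$indel_size > 0)
  shift <- if (marker$variant_type == "insertion") marker$indel_size else -marker$indel_size
  if (product_refers_to == "wild") {
    w <- marker$product_bp; v <- marker$product_bp + shift
  } else {
    v <- marker$product_bp; w <- marker$product_bp - shift
  }
  if (min(w, v) <= 0) stop("non-positive fragment length; check marker definition")
  lens <- switch(as.character(call), "0" = w, "1" = sort(c(w, v)), "2" = v)
  list(fragment_lengths = as.integer(lens), heteroduplex_possible = call == 1L)
}
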