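#' Construct an enrichment matrix
#'
#' The central exchange object of the package: a genes x replicates matrix of
#' log2 enrichment values (IP channel over total-RNA reference, or any
#' analogous log ratio) together with a per-replicate condition label,
#' `"IP"` or `"Mock"`.
#'
#' @param values Numeric matrix, genes in rows and replicates in columns.
#'   Row names are gene identifiers, column names replicate identifiers; both
#'   must be unique. All values must be finite.
#' @param condition Character vector of `"IP"`/`"Mock"` labels, one per
#'   column of `values`. May be named by replicate id; unnamed vectors are
#'   matched positionally.
#'
#' @return An object of class `enrichment_matrix`: a list with elements
#'   `values` (the numeric matrix) and `condition` (named character vector).
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), c("ip1", "ip2", "mock1")))
#' em <- enrichment_matrix(m, c("IP", "IP", "Mock"))
#' n_genes(em)
#' @export
enrichment_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("rep", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values)))
    stop("duplicate replicate ids", call. = FALSE)
  if (nrow(values) > 0 && any(!is.finite(values)))
    stop("non-finite values in enrichment matrix", call. = FALSE)
  if (length(condition) != ncol(values))
    stop("'condition' must have one entry per replicate", call. = FALSE)
  if (!is.null(names(condition))) {
    missing <- setdiff(colnames(values), names(condition))
    if (length(missing))
      stop("replicates missing from condition map: ",
           paste(missing, collapse = ", "), call. = FALSE)
    condition <- condition[colnames(values)]
  }
  condition <- as.character(condition)
  if (!all(condition %in% c("IP", "Mock")))
    stop("condition labels must be 'IP' or 'Mock'", call. = FALSE)
  names(condition) <- colnames(values)
  structure(list(values = values, condition = condition),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d genes x %d replicates (%d IP, %d Mock)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "IP"), sum(x$condition == "Mock")))
  invisible(x)
}

#' @rdname enrichment_matrix
#' @param x An `enrichment_matrix`.
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname enrichment_matrix
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname enrichment_matrix
#' @export
replicate_ids <- function(x) colnames(x$values)

#' Extract the IP or Mock submatrix
#'
#' @param x An [enrichment_matrix()].
#' @param condition `"IP"` or `"Mock"`.
#' @return Numeric matrix of the replicates with that label, column order
#'   preserved.
#' @export
condition_values <- function(x, condition = c("IP", "Mock")) {
  condition <- match.arg(condition)
  x$values[, x$condition == condition, drop = FALSE]
}

#' Read a gene x replicate enrichment matrix from a TSV file
#'
#' Expects a UTF-8 tab-delimited file whose first column (header `gene`)
#' holds gene identifiers and whose remaining columns hold one replicate
#' each. Rows containing missing or non-numeric entries are dropped with a
#' message; gene and replicate order are preserved as found in the file.
#'
#' @param path Path to the TSV file.
#' @param condition_map Named character vector mapping every replicate id in
#'   the header to `"IP"` or `"Mock"`.
#' @return An [enrichment_matrix()]. The number of dropped rows is reported
#'   via `message()` and attached as attribute `"dropped"`.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, condition_map) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2)
    stop("matrix file must have a gene column and at least one replicate",
         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  reps <- colnames(df)[-1]
  missing <- setdiff(reps, names(condition_map))
  if (length(missing))
    stop("replicates absent from condition map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), ncol = length(reps),
                 dimnames = list(ids, reps))
  keep <- rowSums(!is.finite(vals)) == 0
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " row(s) with missing/non-numeric values dropped")
  em <- enrichment_matrix(vals[keep, , drop = FALSE],
                          condition_map[reps])
  attr(em, "dropped") <- dropped
  em
}

#' Write an enrichment matrix to a TSV file
#'
#' Values are written with 6 significant digits; `read_matrix()` on the
#' result reproduces the matrix at that precision. A zero-gene matrix yields
#' a header-only file.
#'
#' @param x An [enrichment_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "enrichment_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x$values)), collapse = "\t"), con)
  if (nrow(x$values) > 0) {
    body <- apply(signif(x$values, 6), 1, function(r)
      paste(format(r, digits = 6, trim = TRUE, scientific = FALSE),
            collapse = "\t"))
    writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Write or read a replicate condition map
#'
#' Sidecar two-column TSV (`replicate`, `condition`) used by the command-line
#' interface so condition labels need not be encoded in column names.
#'
#' @param path Path to a two-column TSV.
#' @return Named character vector of `"IP"`/`"Mock"` labels.
#' @export
read_conditions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("replicate", "condition") %in% colnames(df)))
    stop("condition file needs 'replicate' and 'condition' columns",
         call. = FALSE)
  stats::setNames(df$condition, df$replicate)
}
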