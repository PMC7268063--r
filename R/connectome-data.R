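#' Construct a connectome dataset
#'
#' Bundles a subjects-by-edges feature matrix with subject identifiers, an
#' optional parcellation (node count plus edge index), and zero or more
#' aligned trait vectors. Edge weights are expected on the Fisher-z scale
#' when they originate from correlation matrices.
#'
#' @param features numeric matrix, one row per subject, one column per edge.
#'   Must be free of `NA`/`NaN`/`Inf`.
#' @param subject_ids character vector of identifiers, one per row. Defaults
#'   to `"s1", "s2", ...`.
#' @param n_nodes optional node count of the parcellation. When given, the
#'   number of columns must equal `n_nodes * (n_nodes - 1) / 2` and the edge
#'   index enumerates the strict upper triangle in row-major order.
#' @param traits optional named list of numeric vectors (one value per
#'   subject; `NA` marks a missing measurement).
#'
#' @return an object of class `connectome_dataset` with elements `features`,
#'   `subject_ids`, `n_nodes`, `edge_index` and `traits`.
#' @seealso [load_edge_table()], [attach_traits()], [vectorize_upper_triangle()]
#' @export
connectome_dataset <- function(features, subject_ids = NULL, n_nodes = NULL,
                               traits = list()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features) || any(!is.finite(features)))
    stop("features must be finite: NaN/Inf edge weights are not allowed")
  n <- nrow(features)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n)
    stop("subject_ids length (", length(subject_ids),
         ") does not match the feature row count (", n, ")")
  edge_index <- NULL
  if (!is.null(n_nodes)) {
    n_nodes <- as.integer(n_nodes)
    e_expect <- n_nodes * (n_nodes - 1) / 2
    if (ncol(features) != e_expect)
      stop("with n_nodes = ", n_nodes, " expected ", e_expect,
           " edges, got ", ncol(features))
    edge_index <- upper_tri_index(n_nodes)
  }
  traits <- lapply(traits, as.numeric)
  for (nm in names(traits))
    if (length(traits[[nm]]) != n)
      stop("trait '", nm, "' has length ", length(traits[[nm]]),
           ", expected ", n)
  structure(list(features = features, subject_ids = subject_ids,
                 n_nodes = n_nodes, edge_index = edge_index,
                 traits = traits),
            class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat("connectome_dataset: ", nrow(x$features), " subjects x ",
      ncol(x$features), " edges", sep = "")
  if (!is.null(x$n_nodes)) cat(" (", x$n_nodes, " nodes)", sep = "")
  cat("\n")
  if (length(x$traits))
    cat("traits:", paste(names(x$traits), collapse = ", "), "\n")
  invisible(x)
}

#' Row-major strict upper-triangle edge index
#'
#' Enumerates the node pairs (i, j), i < j, in row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ... This single ordering is the
#' package-wide convention for edge (feature) indices.
#'
#' @param n_nodes node count.
#' @return integer matrix with columns `node_i`, `node_j`.
#' @export
upper_tri_index <- function(n_nodes) {
  n <- as.integer(n_nodes)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(node_i = i, node_j = j)
}

#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Reduces a symmetric connectivity matrix to its edge vector, taking the
#' strict upper triangle in row-major order ((1,2), (1,3), ..., (2,3), ...).
#' The diagonal is ignored.
#'
#' @param m square numeric matrix, symmetric within `tol`.
#' @param tol absolute tolerance for the symmetry check.
#' @return numeric vector of length `n * (n - 1) / 2`.
#' @export
vectorize_upper_triangle <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m))
    stop("matrix is not square: ", nrow(m), " x ", ncol(m))
  asym <- abs(m - t(m)) > tol
  if (any(asym)) {
    bad <- which(asym, arr.ind = TRUE)[1L, ]
    stop("matrix is not symmetric: entry (", min(bad), ",", max(bad),
         ") differs from its transpose by more than ", tol)
  }
  tm <- t(m)
  tm[lower.tri(tm)] # column-major lower triangle of t(m) == row-major upper
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper_triangle()] up to the diagonal, which is set
#' to `diag_value`.
#'
#' @param edges edge vector in row-major upper-triangle order.
#' @param n_nodes node count; `length(edges)` must equal `n_nodes*(n_nodes-1)/2`.
#' @param diag_value value placed on the diagonal (default 0).
#' @return symmetric `n_nodes` x `n_nodes` matrix.
#' @export
edges_to_matrix <- function(edges, n_nodes, diag_value = 0) {
  e_expect <- n_nodes * (n_nodes - 1) / 2
  if (length(edges) != e_expect)
    stop("expected ", e_expect, " edges for n_nodes = ", n_nodes,
         ", got ", length(edges))
  m <- matrix(diag_value, n_nodes, n_nodes)
  tm <- t(m)
  tm[lower.tri(tm)] <- edges
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Load an edge table (netmats dialect)
#'
#' Reads a plain-text table with one subject per row, whitespace- or
#' comma-delimited. Rows may be pre-vectorized edge vectors (length E) or
#' flattened full `n_nodes` x `n_nodes` matrices (length `n_nodes^2`, detected
#' when `n_nodes` is declared); flattened matrices are symmetrized through
#' [vectorize_upper_triangle()]. Constant (zero-variance) columns are kept --
#' so feature indices stay stable -- but reported via a message.
#'
#' @param path file path.
#' @param n_nodes optional declared node count.
#' @param subject_ids optional identifiers (default `"s1", ...`).
#' @return a [connectome_dataset()] (features only, no traits).
#' @export
load_edge_table <- function(path, n_nodes = NULL, subject_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no rows in ", path)
  parse_row <- function(ln) {
    fields <- strsplit(trimws(ln), "[,[:space:]]+")[[1L]]
    out <- suppressWarnings(as.numeric(fields))
    if (anyNA(out))
      stop("non-numeric or NaN entry in edge table (value '",
           fields[which(is.na(out))[1L]], "')")
    if (any(!is.finite(out))) stop("non-finite entry in edge table")
    out
  }
  rows <- lapply(lines, parse_row)
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("ragged edge table: row lengths ", paste(unique(lens), collapse = ", "))
  width <- lens[1L]
  feats <- do.call(rbind, rows)
  if (!is.null(n_nodes)) {
    n_nodes <- as.integer(n_nodes)
    e_expect <- n_nodes * (n_nodes - 1) / 2
    if (width == n_nodes^2) {
      feats <- t(apply(feats, 1L, function(r)
        vectorize_upper_triangle(matrix(r, n_nodes, n_nodes, byrow = TRUE))))
    } else if (width != e_expect) {
      stop("row length ", width, " is neither n_nodes^2 = ", n_nodes^2,
           " nor n_nodes*(n_nodes-1)/2 = ", e_expect)
    }
  }
  const <- which(apply(feats, 2L, function(col) max(col) == min(col)))
  if (length(const))
    message(length(const), " zero-variance edge column(s) retained: ",
            paste(head(const, 10L), collapse = ", "),
            if (length(const) > 10L) ", ..." else "")
  connectome_dataset(feats, subject_ids = subject_ids, n_nodes = n_nodes)
}

#' Attach a trait to a dataset, dropping subjects with missing values
#'
#' Subjects whose value for `trait_name` is missing -- or who are absent from
#' the trait table altogether -- are removed from the returned dataset, so
#' the effective sample size is trait-specific. Surviving subjects keep
#' their original order.
#'
#' @param dataset a [connectome_dataset()].
#' @param trait_table data frame whose first column holds subject IDs, with
#'   one column per trait (empty or `NA` = missing), or a path to such a CSV.
#' @param trait_name name of the trait column to attach.
#' @return the filtered dataset with `traits[[trait_name]]` populated.
#' @export
attach_traits <- function(dataset, trait_table, trait_name) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  if (is.character(trait_table) && length(trait_table) == 1L)
    trait_table <- read.csv(trait_table, stringsAsFactors = FALSE)
  if (!trait_name %in% names(trait_table))
    stop("trait '", trait_name, "' not found in trait table")
  ids <- as.character(trait_table[[1L]])
  vals <- suppressWarnings(as.numeric(trait_table[[trait_name]]))
  pos <- match(dataset$subject_ids, ids)
  unmatched <- sum(is.na(pos))
  if (unmatched > 0L)
    warning(unmatched, " subject(s) absent from the trait table; ",
            "treated as missing and dropped")
  trait <- rep(NA_real_, length(dataset$subject_ids))
  trait[!is.na(pos)] <- vals[pos[!is.na(pos)]]
  keep <- !is.na(trait)
  if (!any(keep)) stop("no subjects remain after dropping missing '",
                       trait_name, "' values")
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " subject(s) dropped for missing '", trait_name, "'")
  out <- connectome_dataset(dataset$features[keep, , drop = FALSE],
                            subject_ids = dataset$subject_ids[keep],
                            n_nodes = dataset$n_nodes)
  out$traits <- lapply(dataset$traits, function(tr) tr[keep])
  out$traits[[trait_name]] <- trait[keep]
  out
}

#' Fisher z-transform of correlations
#'
#' `atanh(r)`, the variance-stabilizing transform that approximately
#' Gaussianizes Pearson correlations. Vectorized; provided for users
#' supplying raw correlation matrices (HCP netmats arrive pre-transformed).
#'
#' @param r correlations with `|r| < 1` (element-wise).
#' @return z-values of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}
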