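#' Readers and writers for the package's delimited-text formats
#'
#' All interchange files are delimited text (comma or tab autodetected on
#' read, comma written), with machine-facing numeric output at 17
#' significant digits so every round trip is bit exact.
#'
#' @name pdheat-io
NULL

detect_sep <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (grepl("\t", line1)) "\t" else ","
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' @describeIn pdheat-io Read a 2-D point cloud (columns x, y).
#' @param path file path.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path))
  if (ncol(df) < 2) stop("point cloud file needs columns x, y")
  bad <- which(!stats::complete.cases(df[, 1:2]) |
                 !vapply(seq_len(nrow(df)),
                         function(r) all(is.finite(as.numeric(df[r, 1:2]))),
                         logical(1)))
  if (length(bad))
    stop("malformed point cloud rows (1-based, excluding header): ",
         paste(bad, collapse = ", "))
  point_cloud(as.matrix(df[, 1:2]), label = basename(path))
}

#' @describeIn pdheat-io Write a point cloud.
#' @param cloud a [point_cloud()].
#' @export
write_point_cloud <- function(cloud, path) {
  df <- data.frame(x = fmt_num(cloud$points[, 1]),
                   y = fmt_num(cloud$points[, 2]))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn pdheat-io Read a symmetric weight matrix, with an optional
#'   header row/column of node labels.
#' @param tol symmetry tolerance.
#' @export
read_network <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  if (has_header) {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    w <- as.matrix(df)
    ids <- rownames(df)
  } else {
    w <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
    ids <- NULL
  }
  dimnames(w) <- NULL
  weighted_network(w, node_ids = ids, tol = tol)
}

#' @describeIn pdheat-io Write a network with node labels.
#' @param network a [weighted_network()].
#' @export
write_network <- function(network, path) {
  w <- network$weights
  df <- as.data.frame(matrix(fmt_num(w), nrow(w)))
  colnames(df) <- network$node_ids
  df <- cbind(id = network$node_ids, df)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn pdheat-io Read a persistence diagram file with header columns
#'   `dimension`, `birth`, `death`; extra columns are ignored with a note.
#' @param dimension which homology dimension to extract (default: all rows,
#'   returned as a list split by dimension).
#' @export
read_pd <- function(path, dimension = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path))
  need <- c("dimension", "birth", "death")
  if (!all(need %in% names(df)))
    stop("persistence diagram file needs columns dimension, birth, death")
  extra <- setdiff(names(df), need)
  if (length(extra))
    message("ignoring extra columns: ", paste(extra, collapse = ", "))
  bad <- which(df$death <= df$birth)
  if (length(bad))
    stop("rows with death <= birth (1-based, excluding header): ",
         paste(bad, collapse = ", "))
  if (!is.null(dimension)) {
    sub <- df[df$dimension == dimension, , drop = FALSE]
    return(persistence_diagram(cbind(sub$birth, sub$death), dimension))
  }
  lapply(split(df, df$dimension), function(sub)
    persistence_diagram(cbind(sub$birth, sub$death), sub$dimension[1]))
}

#' @describeIn pdheat-io Write one or more persistence diagrams.
#' @param pds a `persistence_diagram` or list of them.
#' @export
write_pd <- function(pds, path) {
  if (inherits(pds, "persistence_diagram")) pds <- list(pds)
  rows <- do.call(rbind, lapply(pds, function(pd) {
    if (!nrow(pd$points)) return(NULL)
    data.frame(dimension = pd$dimension,
               birth = fmt_num(pd$points[, 1]),
               death = fmt_num(pd$points[, 2]))
  }))
  if (is.null(rows))
    rows <- data.frame(dimension = integer(0), birth = character(0),
                       death = character(0))
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn pdheat-io Write a list of coefficient vectors (one diagram
#'   per row: `basis_id`, `n_points`, `f_0..f_kappa`); round-trips exactly.
#' @param coeff_list list of [fourier_coefficients()].
#' @export
write_coefficients <- function(coeff_list, path) {
  if (inherits(coeff_list, "hk_coefficients")) coeff_list <- list(coeff_list)
  Fm <- coefficient_matrix(coeff_list)
  df <- data.frame(basis_id = vapply(coeff_list, `[[`, "", "basis_id"),
                   n_points = vapply(coeff_list, `[[`, 0L, "n_points"))
  co <- as.data.frame(matrix(fmt_num(Fm), nrow(Fm)))
  colnames(co) <- paste0("f_", seq_len(ncol(Fm)) - 1L)
  utils::write.table(cbind(df, co), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @describeIn pdheat-io Read a coefficient file back into a list of
#'   `hk_coefficients`.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path))
  fcols <- grep("^f_", names(df))
  lapply(seq_len(nrow(df)), function(r)
    structure(list(coefficients = as.numeric(df[r, fcols]),
                   kappa = length(fcols) - 1L,
                   basis_id = as.character(df$basis_id[r]),
                   n_points = as.integer(df$n_points[r])),
              class = "hk_coefficients"))
}

#' @describeIn pdheat-io Cache a solved eigenbasis (single archive; the one
#'   binary format in the package, for bit-reproducible reuse downstream).
#' @param basis an [lb_basis].
#' @export
write_basis_cache <- function(basis, path) {
  stopifnot(inherits(basis, "lb_basis"))
  saveRDS(basis, path)
  invisible(path)
}

#' @describeIn pdheat-io Restore a cached eigenbasis.
#' @export
read_basis_cache <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  basis <- readRDS(path)
  if (!inherits(basis, "lb_basis")) stop("not a basis cache: ", path)
  basis
}

#' @describeIn pdheat-io Export eigenvalues as plain text for inspection.
#' @export
export_eigenvalues <- function(basis, path) {
  utils::write.table(
    data.frame(k = seq_along(basis$eigenvalues) - 1L,
               lambda = fmt_num(basis$eigenvalues)),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
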