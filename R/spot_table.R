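#' Spot tables
#'
#' A `spot_table` holds one row per detected RNA molecule ("spot"): its
#' physical 2D or 3D coordinates and a categorical gene tag.  It is the input
#' of every stage of the segmentation pipeline.
#'
#' @param coords numeric matrix, one row per spot, 2 or 3 columns
#'   (`x`, `y`\[, `z`\]) in physical units (pixels or micrometres; the pipeline
#'   is unit-agnostic).
#' @param gene character or integer vector of gene tags, one per spot.  Gene
#'   names are factorized into a stable, lexicographically sorted vocabulary;
#'   codes are 1-based (`1..L`).
#' @param spot_ids optional vector of unique spot identifiers; defaults to
#'   `1..N` as character.
#'
#' @return An object of class `spot_table`: a list with elements
#'   * `coords`: the `N x dim` coordinate matrix,
#'   * `gene_ids`: integer codes in `1..L`,
#'   * `gene_names`: the length-`L` vocabulary,
#'   * `spot_ids`: unique spot identifiers.
#' @examples
#' st <- spot_table(cbind(x = c(0, 1, 2), y = c(0, 0, 1)),
#'                  gene = c("Gad1", "Slc17a7", "Gad1"))
#' st$gene_names
#' @export
spot_table <- function(coords, gene, spot_ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n > 0 && !ncol(coords) %in% c(2L, 3L)) {
    stop("coords must have 2 or 3 columns, got ", ncol(coords))
  }
  if (n > 0 && !all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1L, all))[1L]
    stop("non-finite coordinate at row ", bad)
  }
  if (length(gene) != n) {
    stop("gene has length ", length(gene), " but coords has ", n, " rows")
  }
  if (is.null(spot_ids)) spot_ids <- as.character(seq_len(n))
  spot_ids <- as.character(spot_ids)
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")
  f <- factor(as.character(gene))  # levels sorted: stable vocabulary
  if (n > 0 && anyNA(f)) stop("missing gene tag at row ", which(is.na(f))[1L])
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  structure(
    list(coords = coords,
         gene_ids = as.integer(f),
         gene_names = levels(f),
         spot_ids = spot_ids),
    class = "spot_table")
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d spots, %dD, %d gene tags\n",
              n_spots(x), spot_dim(x), length(x$gene_names)))
  invisible(x)
}

#' @rdname spot_table
#' @param x a `spot_table`.
#' @export
n_spots <- function(x) nrow(x$coords)

#' @rdname spot_table
#' @export
spot_dim <- function(x) ncol(x$coords)

#' Subset a spot table by row
#'
#' @param x a `spot_table`.
#' @param i integer or logical row index.
#' @param ... unused.
#' @return A `spot_table` with the selected spots; the gene vocabulary is kept
#'   unchanged so gene codes remain comparable across subsets.
#' @export
`[.spot_table` <- function(x, i, ...) {
  out <- x
  out$coords <- x$coords[i, , drop = FALSE]
  out$gene_ids <- x$gene_ids[i]
  out$spot_ids <- x$spot_ids[i]
  out
}

#' Read a spot table from a delimited text file
#'
#' Reads a headered CSV/TSV file with one row per spot and maps its columns
#' onto the `spot_table` fields.  The gene column may contain names or integer
#' codes; either way the values are factorized into a sorted vocabulary, so
#' loading the same file twice yields identical objects.
#'
#' @param path path to a CSV or TSV file.  The delimiter is chosen from the
#'   extension (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param column_map named character vector mapping the roles
#'   `x`, `y`, `z`, `gene`, `spot_id` to column names in the file.  `z` and
#'   `spot_id` are optional; defaults are the role names themselves.
#' @param sep field delimiter override.
#' @return A [spot_table]; row order of the file is preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x = c(0, 1), y = c(0, 2), gene = c("a", "b")),
#'           f, row.names = FALSE)
#' load_spots(f)
#' @export
load_spots <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "")
  cmap <- c(x = "x", y = "y", z = "z", gene = "gene", spot_id = "spot_id")
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown)) stop("unknown column_map roles: ",
                              paste(unknown, collapse = ", "))
    cmap[names(column_map)] <- column_map
  }
  need <- c("x", "y", "gene")
  for (role in need) {
    if (!cmap[[role]] %in% names(df)) {
      stop("required column '", cmap[[role]], "' (role ", role,
           ") not found in ", path)
    }
  }
  dims <- c("x", "y")
  if (cmap[["z"]] %in% names(df)) dims <- c(dims, "z")
  coords <- sapply(dims, function(role) {
    raw <- df[[cmap[[role]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad)) {
      stop("non-numeric ", role, " coordinate '", raw[bad[1L]],
           "' at data row ", bad[1L], " of ", path)
    }
    val
  })
  coords <- matrix(coords, ncol = length(dims),
                   dimnames = list(NULL, dims))
  ids <- if (cmap[["spot_id"]] %in% names(df)) df[[cmap[["spot_id"]]]] else NULL
  spot_table(coords, gene = df[[cmap[["gene"]]]], spot_ids = ids)
}

#' Write a spot table to a delimited text file
#'
#' @param spots a [spot_table].
#' @param path output path; `.tsv`/`.txt` extension selects tab delimiting.
#' @param sep field delimiter override.
#' @return `path`, invisibly.
#' @export
write_spots <- function(spots, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  # %.17g guarantees the printed text parses back to the identical double
  num <- apply(spots$coords, 2L, function(v) sprintf("%.17g", v))
  if (n_spots(spots) == 1L) num <- matrix(num, nrow = 1L,
                                          dimnames = list(NULL,
                                                          colnames(spots$coords)))
  df <- data.frame(spot_id = spots$spot_ids, num,
                   gene = spots$gene_names[spots$gene_ids],
                   check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove isolated spots by nearest-neighbor distance
#'
#' Preprocessing step run before any feature computation: the Euclidean
#' distance from each spot to its nearest neighbor is computed, and spots
#' whose nearest-neighbor distance exceeds a threshold are treated as
#' outliers and removed.  The threshold is either absolute (`threshold`) or a
#' quantile of the nearest-neighbor-distance distribution (`quantile`,
#' default 0.99 — a scale-free default that removes only extreme isolates).
#'
#' Filtering is a single pass.  With an absolute threshold the operation is
#' idempotent only when nothing was removed: removing a spot can increase the
#' nearest-neighbor distance of the spots it was closest to, so a second pass
#' may remove more.
#'
#' @param spots a [spot_table] with at least 2 spots.
#' @param threshold absolute distance threshold (overrides `quantile`).
#' @param quantile quantile of the nearest-neighbor-distance distribution
#'   used when `threshold` is `NULL`.
#' @return A list with elements `spots` (the surviving [spot_table]),
#'   `removed_ids` (spot ids filtered out), `kept` (logical keep mask over the
#'   input rows), `nn_dist` (per-input-spot nearest-neighbor distance) and
#'   `threshold_used`.
#' @examples
#' st <- spot_table(cbind(c(0, 1, 2, 100), c(0, 0, 0, 0)), gene = rep("g", 4))
#' filter_outliers(st, threshold = 2)$removed_ids
#' @export
filter_outliers <- function(spots, threshold = NULL, quantile = 0.99) {
  n <- n_spots(spots)
  if (n < 2L) stop("filter_outliers needs at least 2 spots (nearest-neighbor ",
                   "distance is undefined for N < 2)")
  nn <- nearest_neighbor_dist(spots$coords)
  if (is.null(threshold)) {
    if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
      stop("quantile must lie in (0, 1)")
    }
    threshold <- as.numeric(stats::quantile(nn, quantile, names = FALSE))
  }
  if (threshold <= 0) stop("threshold must be positive")
  keep <- nn <= threshold
  list(spots = spots[keep],
       removed_ids = spots$spot_ids[!keep],
       kept = keep,
       nn_dist = nn,
       threshold_used = threshold)
}

# Euclidean nearest-neighbor distance of every row of a coordinate matrix,
# computed in row chunks so memory stays O(chunk * N).
nearest_neighbor_dist <- function(coords, chunk = 512L) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # squared distances chunk x N via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE],
                                                   coords)
    d2[cbind(seq_along(idx), idx)] <- Inf   # exclude self
    out[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}
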