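#' Assemble a spot-level spatial transcriptomics dataset
#'
#' The unified input object of the package: a spot x gene count matrix with
#' per-spot spatial coordinates and, optionally, categorical region labels,
#' RGB image patches (one per spot) and a slice index for multi-slice (3D)
#' experiments.
#'
#' @param counts integer matrix, spots x genes, non-negative. Row names are
#'   taken as spot ids and column names as gene ids when `spot_ids` /
#'   `gene_ids` are not given.
#' @param coords numeric matrix with 2 (x, y) or 3 (x, y, z) columns, one row
#'   per spot, in the units of the input file (no pixel convention imposed;
#'   the graph thresholds `lambda`, `mu`, `xi` are interpreted in the same
#'   units).
#' @param spot_ids,gene_ids unique character vectors.
#' @param labels optional per-spot region annotation; `NA` marks unlabeled
#'   spots (weak supervision).
#' @param patches optional numeric array `spots x px x px x 3` with values in
#'   `[0, 1]`.
#' @param slice_id optional integer vector, one entry per spot.
#'
#' @return An object of class `spot_dataset`.
#' @export
spot_dataset <- function(counts, coords, spot_ids = rownames(counts),
                         gene_ids = colnames(counts), labels = NULL,
                         patches = NULL, slice_id = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  spot_ids <- as.character(spot_ids); gene_ids <- as.character(gene_ids)
  if (anyDuplicated(spot_ids)) stop("duplicated spot ids: ",
    paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids: ",
    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (nrow(counts) != length(spot_ids))
    stop("counts has ", nrow(counts), " rows but ", length(spot_ids), " spot ids")
  if (ncol(counts) != length(gene_ids))
    stop("counts has ", ncol(counts), " columns but ", length(gene_ids), " gene ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (nrow(coords) != nrow(counts))
    stop("coords rows must match number of spots")
  if (!ncol(coords) %in% c(2L, 3L)) stop("coords must have 2 or 3 columns")
  if (any(!is.finite(coords))) stop("coords must be finite")
  if (!is.null(labels)) {
    if (length(labels) != nrow(counts)) stop("labels length must match spots")
    labels <- as.character(labels)
  }
  if (!is.null(slice_id)) {
    if (length(slice_id) != nrow(counts)) stop("slice_id length must match spots")
    slice_id <- as.integer(slice_id)
  }
  if (!is.null(patches)) {
    d <- dim(patches)
    if (length(d) != 4L || d[1] != nrow(counts) || d[2] != d[3] || d[4] != 3L)
      stop("patches must be an array spots x px x px x 3")
  }
  dimnames(counts) <- list(spot_ids, gene_ids)
  structure(list(counts = counts, coords = coords, spot_ids = spot_ids,
                 gene_ids = gene_ids, labels = labels, patches = patches,
                 slice_id = slice_id),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat("spot_dataset:", nrow(x$counts), "spots x", ncol(x$counts), "genes\n")
  cat("  coords:", ncol(x$coords), "D")
  if (!is.null(x$slice_id)) cat(";", length(unique(x$slice_id)), "slices")
  cat("\n")
  if (!is.null(x$labels))
    cat("  labels:", sum(!is.na(x$labels)), "annotated of", length(x$labels), "\n")
  if (!is.null(x$patches))
    cat("  patches:", dim(x$patches)[2], "x", dim(x$patches)[3], "px RGB\n")
  invisible(x)
}

#' Pipeline configuration with defaults
#'
#' All tunables of the pipeline in one place. Defaults follow the method's
#' published operating point: spatial-graph thresholds `lambda = 200` and
#' `mu = 10` (distance units of the coordinate file), autoencoder layout
#' 2000 hidden-variable genes with a `[hvg, 1000, 50, 1000, hvg]` frame,
#' learning rate 8e-5 with weight decay 1e-6, conditional-network defaults
#' `alpha = 0.5`, `boxsize = 1.5`, `kk = 1`, classification loss weight 8 in
#' the per-view graph encoder, and 15 nearest neighbours for spatial
#' pseudo-expression.
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class `spotfuse_config`.
#' @export
spotfuse_config <- function(...) {
  cfg <- list(
    hvg_count = 2000L,          # variable genes kept for the autoencoder
    ae_hidden = 1000L,          # autoencoder hidden width
    ae_latent = 50L,            # autoencoder latent width
    ae_lr = 8e-5,
    ae_weight_decay = 1e-6,
    ae_epochs = 200L,
    ae_dropout = 0.1,
    simclr_tau = 0.5,           # NT-Xent temperature
    patch_px = 32L,             # patch edge length in pixels
    visual_dim = 64L,           # visual feature width
    visual_epochs = 40L,
    lambda = 200,               # SLG: max planar distance for an edge channel
    mu = 10,                    # SLG: max |dy| for an edge channel
    xi = NULL,                  # 3D SLG: max |dz|; defaults to the slice gap
    slg_e3_rule = "le",         # "le": e3 = 1 iff |dy| <= mu (or "gt")
    knn_edges = 6L,             # symmetric k-NN graph degree
    ccsn_alpha = 0.5,           # conditional-network significance level
    ccsn_boxsize = 1.5,         # expression window, in per-gene sd units
    ccsn_kk = 1L,               # number of conditioning (hub) genes
    gag_genes = 100L,           # genes entering the association network
    egat_dims = c(128L, 32L),   # per-layer output widths of the graph encoder
    egat_epochs = 120L,
    egat_lr = 1e-3,
    egat_loss_weight = 8,       # weight of the classification term
    egat_leaky_slope = 0.2,
    gam_width = 32L,            # common latent width for fusion
    gam_reduction = 4,          # channel-attention reduction ratio
    gam_kernel = 7L,            # spatial-attention kernel length
    gam_epochs = 150L,
    gam_lr = 1e-3,
    label_frac = 0.7,           # fraction of spots used as weak supervision
    spe_k = 15L,                # neighbours for spatial pseudo-expression
    spe_include_self = FALSE,
    cluster_k = NULL,           # fixed cluster count; NULL = select by DBI
    k_range = 2:8,
    fdr = 0.05,
    lfc_min = 0,                # optional |log2FC| gate on top of FDR
    mean_head = "softmax",      # AE mean head: "softmax" or "softplus"
    seed = 0L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$hvg_count > 0, cfg$ae_latent > 0, cfg$spe_k >= 1,
            cfg$fdr > 0, cfg$fdr < 1, cfg$lambda > 0, cfg$mu > 0,
            cfg$knn_edges >= 1, cfg$ccsn_boxsize > 0, cfg$simclr_tau > 0)
  class(cfg) <- "spotfuse_config"
  cfg
}

#' Read a config file of `key: value` lines
#'
#' Lines starting with `#` and blank lines are ignored. Values are parsed as
#' numbers where possible, `true`/`false` as logicals, comma-separated values
#' as vectors.
#'
#' @param path file path.
#' @return A `spotfuse_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    raw <- trimws(paste(kv[-1], collapse = ":"))
    parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    val <- suppressWarnings(as.numeric(parts))
    if (any(is.na(val))) {
      val <- if (all(tolower(parts) %in% c("true", "false")))
        as.logical(toupper(parts)) else parts
    }
    if (identical(val, "NULL")) val <- NULL
    over[[key]] <- val
  }
  do.call(spotfuse_config, over)
}

#' Load a spot x gene expression matrix
#'
#' Accepts Matrix Market coordinate files (with separate gene and barcode id
#' files, 10x convention genes x spots, transposed on load) or dense
#' delimited tables with spot rows and a header of gene names. MTX
#' orientation is auto-detected by matching dimensions against the id files;
#' an ambiguous square matrix is taken as genes x spots with a warning.
#'
#' @param matrix_path path to `.mtx` or a dense CSV/TSV.
#' @param genes_path,barcodes_path one id per line; required for MTX input.
#' @return A list with elements `counts` (spots x genes), `spot_ids`,
#'   `gene_ids`.
#' @export
load_expression <- function(matrix_path, genes_path = NULL, barcodes_path = NULL) {
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(barcodes_path))
      stop("MTX input needs genes_path and barcodes_path")
    m <- as.matrix(Matrix::readMM(matrix_path))
    genes <- readLines(genes_path, warn = FALSE)
    barcodes <- readLines(barcodes_path, warn = FALSE)
    if (anyDuplicated(genes)) stop("duplicated gene ids in ", genes_path)
    if (anyDuplicated(barcodes)) stop("duplicated spot ids in ", barcodes_path)
    if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
      if (nrow(m) == ncol(m))
        warning("square MTX; assuming genes x spots orientation")
      m <- t(m)
    } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
      # already spots x genes
    } else {
      stop("MTX dimensions ", nrow(m), "x", ncol(m),
           " match neither orientation of ", length(genes), " genes x ",
           length(barcodes), " spots")
    }
    dimnames(m) <- list(barcodes, genes)
  } else {
    sep <- if (grepl("\\.tsv$|\\.txt$", matrix_path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                            row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
    if (anyDuplicated(rownames(m))) stop("duplicated spot ids in ", matrix_path)
  }
  if (any(m < 0) || any(m != round(m)))
    stop("expression matrix must contain non-negative integer counts")
  storage.mode(m) <- "double"
  list(counts = m, spot_ids = rownames(m), gene_ids = colnames(m))
}

#' Load the spot table (coordinates, optional slice and labels)
#'
#' Expects a delimited table with columns `id`, `x`, `y` and optionally `z`,
#' `slice`, `label`. Rows are aligned to `spot_ids` by id join, so on-disk
#' order is irrelevant.
#'
#' @param path CSV/TSV file.
#' @param spot_ids spot order to align to (from [load_expression()]).
#' @return list with `coords`, and `labels` / `slice_id` when present.
#' @export
load_spots <- function(path, spot_ids) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(df)))
    stop("spot table must have columns id, x, y")
  df$id <- as.character(df$id)
  missing <- setdiff(spot_ids, df$id)
  if (length(missing))
    stop("spots missing from coordinate table: ", paste(missing, collapse = ", "))
  df <- df[match(spot_ids, df$id), , drop = FALSE]
  coords <- as.matrix(df[, c("x", "y", if ("z" %in% names(df)) "z")])
  rownames(coords) <- spot_ids
  out <- list(coords = coords)
  if ("slice" %in% names(df)) out$slice_id <- as.integer(df$slice)
  if ("label" %in% names(df)) {
    lab <- as.character(df$label)
    lab[lab %in% c("", "NA", "unlabeled")] <- NA_character_
    out$labels <- lab
  }
  out
}

read_image_any <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

reflect_index <- function(idx, n) {
  # reflect out-of-range indices back into 1..n (mirror padding)
  idx <- ((idx - 1L) %% (2L * n))
  idx <- ifelse(idx >= n, 2L * n - 1L - idx, idx)
  idx + 1L
}

#' Load per-spot image patches
#'
#' Either reads one tile file per spot (`<spot id>.png` / `.tif` in a
#' directory) or crops square patches from a single whole-slide image,
#' centred on each spot's pixel coordinates. Crops extending past the image
#' border are reflection-padded (with a warning).
#'
#' @param path tile directory or whole-image file.
#' @param spot_ids spot order.
#' @param pixel_coords spots x 2 matrix of (row, col) pixel centres; required
#'   for whole-image input.
#' @param patch_px patch edge length in pixels.
#' @return array `spots x patch_px x patch_px x 3` in `[0, 1]`.
#' @export
load_patches <- function(path, spot_ids, pixel_coords = NULL, patch_px = 32L) {
  n <- length(spot_ids)
  out <- array(0, c(n, patch_px, patch_px, 3L))
  if (dir.exists(path)) {
    for (i in seq_len(n)) {
      cand <- file.path(path, paste0(spot_ids[i], c(".png", ".tif", ".tiff")))
      hit <- cand[file.exists(cand)]
      if (!length(hit)) stop("no patch image found for spot ", spot_ids[i])
      img <- read_image_any(hit[1])
      if (any(dim(img)[1:2] != patch_px))
        stop("patch for spot ", spot_ids[i], " is not ", patch_px, "x", patch_px)
      out[i, , , ] <- img
    }
  } else {
    if (is.null(pixel_coords)) stop("whole-image input needs pixel_coords")
    img <- read_image_any(path)
    h <- dim(img)[1]; w <- dim(img)[2]
    half <- patch_px %/% 2L
    padded <- FALSE
    for (i in seq_len(n)) {
      r0 <- round(pixel_coords[i, 1]) - half
      c0 <- round(pixel_coords[i, 2]) - half
      ri <- r0 + seq_len(patch_px) - 1L
      ci <- c0 + seq_len(patch_px) - 1L
      if (any(ri < 1L | ri > h | ci < 1L | ci > w)) padded <- TRUE
      out[i, , , ] <- img[reflect_index(ri, h), reflect_index(ci, w), ]
    }
    if (padded) warning("some patches extended past the image border; reflection-padded")
  }
  dimnames(out) <- list(spot_ids, NULL, NULL, NULL)
  out
}

#' Write a dataset to disk in the formats the loaders read
#'
#' Produces `matrix.mtx` (genes x spots, 10x convention), `genes.txt`,
#' `barcodes.txt`, `spots.csv`, and per-spot PNG tiles under `patches/` when
#' present.
#'
#' @param ds a `spot_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spot_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(ds$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(dir, "genes.txt"))
  writeLines(ds$spot_ids, file.path(dir, "barcodes.txt"))
  df <- data.frame(id = ds$spot_ids, x = ds$coords[, 1], y = ds$coords[, 2])
  if (ncol(ds$coords) == 3L) df$z <- ds$coords[, 3]
  if (!is.null(ds$slice_id)) df$slice <- ds$slice_id
  if (!is.null(ds$labels)) df$label <- ifelse(is.na(ds$labels), "", ds$labels)
  utils::write.csv(df, file.path(dir, "spots.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(ds$patches)) {
    pd <- file.path(dir, "patches")
    dir.create(pd, showWarnings = FALSE)
    for (i in seq_along(ds$spot_ids))
      png::writePNG(ds$patches[i, , , ], file.path(pd, paste0(ds$spot_ids[i], ".png")))
  }
  invisible(dir)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @param with_patches read the `patches/` tiles if present.
#' @param patch_px patch edge length.
#' @return A `spot_dataset`.
#' @export
read_dataset <- function(dir, with_patches = TRUE, patch_px = 32L) {
  ex <- load_expression(file.path(dir, "matrix.mtx"),
                        file.path(dir, "genes.txt"),
                        file.path(dir, "barcodes.txt"))
  sp <- load_spots(file.path(dir, "spots.csv"), ex$spot_ids)
  patches <- NULL
  pd <- file.path(dir, "patches")
  if (with_patches && dir.exists(pd))
    patches <- load_patches(pd, ex$spot_ids, patch_px = patch_px)
  spot_dataset(ex$counts, sp$coords, spot_ids = ex$spot_ids,
               gene_ids = ex$gene_ids, labels = sp$labels,
               patches = patches, slice_id = sp$slice_id)
}

#' Write a numeric matrix as TSV with a spot-id index column
#' @param x matrix with row names.
#' @param path output file.
#' @export
write_embedding <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a TSV written by [write_embedding()]
#' @param path file path.
#' @return matrix with spot ids as row names.
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
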