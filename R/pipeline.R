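# End-to-end driver: features -> view graphs -> per-view encoders ->
# fusion -> clustering -> SPE -> dark genes, with a manifest that makes any
# run reproducible bit-for-bit.

available_views <- function(dataset, visual_features) {
  v <- c("SLG", "GAG")
  if (!is.null(dataset$patches) || !is.null(visual_features))
    v <- c("HSG", v)
  v
}

#' Run the full multiview fusion pipeline
#'
#' Executes expression feature learning, optional visual feature learning,
#' view-graph construction (HSG when patches or precomputed visual features
#' are present, SLG always, GAG always), per-view graph attention encoding,
#' attention fusion, k-means clustering (with Davies-Bouldin model
#' selection when `cluster_k` is `NULL`), spatial pseudo-expression, and
#' dark-gene calling. With multi-slice input, `mode = "3d"` builds the
#' spatial graph in (x, y, z) with the 4th adjacent-slice edge channel,
#' while `mode = "2d"` restricts spatial edges to single slices.
#'
#' All randomness derives from `config$seed`; a rerun with the same dataset
#' and manifest reproduces every output exactly.
#'
#' @param dataset a [spot_dataset()].
#' @param config a [spotfuse_config()].
#' @param mode `"auto"` (3D iff the dataset has slices or 3D coordinates),
#'   `"2d"`, or `"3d"`.
#' @param visual_features optional precomputed spots x d matrix replacing
#'   contrastive training for the HSG view.
#' @param views subset of `c("HSG", "SLG", "GAG")` to build (view
#'   ablations); default: all available (HSG requires patches or
#'   `visual_features`).
#' @param allow_single_view proceed when only one view is available
#'   (fusion is skipped; the single view embedding is used directly).
#' @param outdir when given, all artifacts are written there as TSV plus a
#'   `manifest.json`.
#' @param verbose progress messages.
#' @return list of class `spotfuse_result`: `embedding`, `clusters`, `k`,
#'   `spe` (a `spe_matrix`), `sdg_report`, `view_embeddings`, `mode`,
#'   `config`, `manifest`.
#' @export
run_spotfuse <- function(dataset, config = spotfuse_config(),
                         mode = c("auto", "2d", "3d"),
                         visual_features = NULL, views = NULL,
                         allow_single_view = FALSE, outdir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(dataset, "spot_dataset"))
  mode <- match.arg(mode)
  has_z <- ncol(dataset$coords) == 3L || !is.null(dataset$slice_id)
  if (mode == "auto") mode <- if (has_z) "3d" else "2d"
  if (mode == "3d" && !has_z)
    stop("3d mode requires slice_id or 3-column coordinates")
  seed <- config$seed
  say <- function(...) if (verbose) message(...)

  say("expression features")
  hv <- select_hvg(dataset$counts, min(config$hvg_count, ncol(dataset$counts)))
  X0 <- train_expr_ae(hv$counts, hidden = config$ae_hidden,
                      latent = config$ae_latent, epochs = config$ae_epochs,
                      lr = config$ae_lr, weight_decay = config$ae_weight_decay,
                      dropout = config$ae_dropout,
                      mean_head = config$mean_head, seed = seed + 1L)

  labels <- dataset$labels
  weak <- NULL
  if (!is.null(labels) && any(!is.na(labels))) {
    weak <- labels
    if (config$label_frac < 1) {
      ann <- which(!is.na(labels))
      keep <- with_seed_local(seed + 5L, {
        sample(ann, round(config$label_frac * length(ann)))
      })
      weak[setdiff(seq_along(labels), keep)] <- NA
    }
  }

  vnames <- available_views(dataset, visual_features)
  if (!is.null(views)) {
    bad <- setdiff(views, vnames)
    if (length(bad))
      stop("requested view(s) not available: ", paste(bad, collapse = ", "))
    vnames <- views
  }
  graphs <- list()

  if ("HSG" %in% vnames) {
    say("visual features")
    v <- visual_features
    if (is.null(v)) {
      v <- train_contrastive(dataset$patches, labels = weak,
                             d_v = config$visual_dim, tau = config$simclr_tau,
                             epochs = config$visual_epochs,
                             batch_size = min(128L, nrow(dataset$counts)),
                             seed = seed + 2L)
    }
    graphs$HSG <- build_view_graph("HSG", X0, v, config)
  }

  if ("SLG" %in% vnames) {
  say("spatial graph (", mode, ")")
  if (mode == "3d") {
    co <- dataset$coords
    if (ncol(co) == 2L) co <- cbind(co, z = as.numeric(dataset$slice_id))
    graphs$SLG <- build_view_graph("SLG3D", X0, co, config)
  } else {
    graphs$SLG <- build_view_graph("SLG", X0, dataset$coords[, 1:2], config,
                                   slice_id = dataset$slice_id)
  }
  }

  if ("GAG" %in% vnames) {
  say("gene association graph")
  gag_counts <- hv$counts[, seq_len(min(ncol(hv$counts), config$gag_genes)),
                          drop = FALSE]
  cdm <- conditional_degree_matrix(gag_counts, alpha = config$ccsn_alpha,
                                   boxsize = config$ccsn_boxsize,
                                   kk = config$ccsn_kk)
  Vfeat <- train_expr_ae(t(cdm$V), hidden = min(config$ae_hidden, 128L),
                         latent = config$ae_latent,
                         epochs = config$ae_epochs, lr = config$ae_lr,
                         weight_decay = config$ae_weight_decay,
                         dropout = config$ae_dropout,
                         mean_head = config$mean_head, seed = seed + 3L)
  rownames(Vfeat) <- dataset$spot_ids
  graphs$GAG <- build_view_graph("GAG", Vfeat, X0, config)
  }

  if (length(graphs) < 2L && !allow_single_view)
    stop("fewer than 2 views available; fusion undefined ",
         "(set allow_single_view = TRUE to proceed with one view)")

  embs <- list()
  for (i in seq_along(graphs)) {
    say("graph encoder: ", names(graphs)[i])
    embs[[names(graphs)[i]]] <-
      train_egat(graphs[[i]], weak, dims = config$egat_dims,
                 epochs = config$egat_epochs, lr = config$egat_lr,
                 loss_weight = config$egat_loss_weight,
                 slope = config$egat_leaky_slope, seed = seed + 10L + i)
  }
  for (nm in names(embs)) rownames(embs[[nm]]) <- dataset$spot_ids

  if (length(embs) >= 2L) {
    say("fusion")
    if (!is.null(weak)) {
      R <- fuse_views(embs, weak, width = config$gam_width,
                      gamma = config$gam_reduction,
                      kernel = config$gam_kernel,
                      epochs = config$gam_epochs, lr = config$gam_lr,
                      seed = seed + 4L)
    } else {
      # the fusion attention is trained by label cross-entropy; without any
      # labels the views are fused by z-scored concatenation instead
      R <- do.call(cbind, lapply(embs, function(E) {
        s <- apply(E, 2L, stats::sd)
        sweep(sweep(E, 2L, colMeans(E)), 2L, ifelse(s > 0, s, 1), "/")
      }))
    }
  } else {
    R <- embs[[1]]
  }

  say("clustering")
  if (is.null(config$cluster_k)) {
    sel <- select_k_dbi(R, config$k_range, seed = seed + 6L)
    k <- sel$k
  } else {
    k <- as.integer(config$cluster_k)
    sel <- NULL
  }
  clusters <- cluster_spots(R, k, seed = seed + 6L)

  say("spatial pseudo-expression")
  spe <- compute_spe(R, dataset$counts, k_nn = config$spe_k,
                     include_self = config$spe_include_self)

  say("dark genes")
  sdg <- tryCatch(
    call_sdgs(dataset$counts, spe, clusters, fdr = config$fdr,
              lfc_min = config$lfc_min),
    error = function(e) {
      warning("dark-gene calling skipped: ", conditionMessage(e))
      NULL
    })

  manifest <- list(
    package = "spotfuse",
    version = tryCatch(as.character(utils::packageVersion("spotfuse")),
                       error = function(e) "dev"),
    mode = mode,
    views = names(graphs),
    n_spots = nrow(dataset$counts),
    n_genes = ncol(dataset$counts),
    selected_k = k,
    config = unclass(config)
  )
  res <- structure(list(embedding = R, clusters = clusters, k = k,
                        dbi = sel$dbi, spe = spe, sdg_report = sdg,
                        view_embeddings = embs, view_graphs = graphs,
                        mode = mode, config = config, manifest = manifest),
                   class = "spotfuse_result")
  if (!is.null(outdir)) write_result(res, outdir)
  res
}

#' @export
print.spotfuse_result <- function(x, ...) {
  cat("spotfuse_result:", nrow(x$embedding), "spots,",
      length(x$view_embeddings), "views (",
      paste(names(x$view_embeddings), collapse = ", "), "), mode", x$mode,
      "\n  clusters: k =", x$k, "\n")
  if (!is.null(x$sdg_report)) {
    cls <- sdg_gene_classes(x$sdg_report)
    cat("  genes: ", sum(cls == "SVG"), " SVG, ", sum(cls == "SDG"),
        " SDG\n", sep = "")
  }
  invisible(x)
}

#' Persist a pipeline result as TSV artifacts plus a manifest
#' @param res a `spotfuse_result`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_result <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_embedding(res$embedding, file.path(outdir, "embedding.tsv"))
  utils::write.table(
    data.frame(id = names(res$clusters), cluster = as.integer(res$clusters)),
    file.path(outdir, "clusters.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  write_embedding(res$spe$spe, file.path(outdir, "spe.tsv"))
  for (nm in names(res$view_embeddings))
    write_embedding(res$view_embeddings[[nm]],
                    file.path(outdir, paste0("embedding_", nm, ".tsv")))
  if (!is.null(res$sdg_report))
    utils::write.table(res$sdg_report, file.path(outdir, "sdg_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(outdir)
}

#' Re-run the pipeline from a saved manifest
#'
#' Reconstructs the configuration (including the seed) from a
#' `manifest.json` written by [write_result()] and runs the pipeline on the
#' given dataset; outputs are bit-identical to the original run.
#'
#' @param manifest_path path to `manifest.json`.
#' @param dataset the same [spot_dataset()] the original run used.
#' @param outdir optional output directory.
#' @param ... further arguments to [run_spotfuse()].
#' @return A `spotfuse_result`.
#' @export
run_from_manifest <- function(manifest_path, dataset, outdir = NULL, ...) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg_list <- man$config
  cfg_list <- cfg_list[!vapply(cfg_list, is.null, TRUE)]
  ints <- c("hvg_count", "ae_hidden", "ae_latent", "ae_epochs", "patch_px",
            "visual_dim", "visual_epochs", "knn_edges", "ccsn_kk",
            "egat_dims", "egat_epochs", "gam_width", "gam_kernel",
            "gam_epochs", "spe_k", "cluster_k", "k_range", "sdg_n_perm",
            "gag_genes", "seed")
  for (nm in intersect(ints, names(cfg_list)))
    cfg_list[[nm]] <- as.integer(cfg_list[[nm]])
  cfg <- do.call(spotfuse_config, cfg_list)
  run_spotfuse(dataset, cfg, mode = man$mode, views = man$views,
               outdir = outdir, ...)
}
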