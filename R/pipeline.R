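#' End-to-end pipeline configuration
#'
#' Resolved settings for the full train/predict pipeline: input paths,
#' view toggles, the embedding source, and the stage configurations.
#' Views are always assembled in the fixed order ESM, PSSM-CLBP, QLC,
#' RECM-CLBP.
#'
#' @param fasta Path to the input FASTA file.
#' @param pssm_dir Directory holding one `<id>.pssm` ASCII PSSM per
#'   record.
#' @param recm Path to the 20 x 20 energy-contact TSV.
#' @param labels Optional path to a two-column `id<TAB>label` TSV (needed
#'   for training).
#' @param views Character subset of
#'   `c("ESM", "PSSM-CLBP", "QLC", "RECM-CLBP")`.
#' @param embedding `"mock"` or a directory of precomputed `<id>.tsv`
#'   D x L embedding matrices.
#' @param embedding_dim Width of mock embeddings.
#' @param de A [de_config()], or `NULL` to skip weight learning (unit
#'   weights).
#' @param btg A [btg_config()], or `NULL` to skip feature selection.
#' @param classifier An [snbilstm_config()].
#' @param seed Pipeline seed (embeddings, folds).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, pssm_dir, recm, labels = NULL,
                            views = c("ESM", "PSSM-CLBP", "QLC", "RECM-CLBP"),
                            embedding = "mock", embedding_dim = 1280L,
                            de = NULL, btg = NULL,
                            classifier = snbilstm_config(), seed = 1L) {
  views <- match.arg(views, several.ok = TRUE)
  structure(list(fasta = fasta, pssm_dir = pssm_dir, recm = recm,
                 labels = labels, views = views, embedding = embedding,
                 embedding_dim = as.integer(embedding_dim),
                 de = de, btg = btg, classifier = classifier,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Extract the multi-view feature table for a set of sequences
#'
#' Reads the FASTA, per-record PSSMs and the energy matrix, computes the
#' enabled views per record and assembles them into one feature table
#' (blocks in fixed order). Records missing a PSSM or embedding file are
#' reported together in one error.
#'
#' @param cfg A [pipeline_config()].
#' @return A [feature_table()], labelled when `cfg$labels` is set.
#' @export
extract_features <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  records <- read_fasta(cfg$fasta)
  ids <- vapply(records, `[[`, character(1), "id")
  needs_pssm <- "PSSM-CLBP" %in% cfg$views
  needs_recm <- "RECM-CLBP" %in% cfg$views
  if (needs_pssm) {
    pssm_paths <- file.path(cfg$pssm_dir, paste0(ids, ".pssm"))
    missing <- ids[!file.exists(pssm_paths)]
    if (length(missing) > 0L) {
      stop(sprintf("missing PSSM file(s) for: %s",
                   paste(missing, collapse = ", ")))
    }
  }
  if (cfg$embedding != "mock" && "ESM" %in% cfg$views) {
    emb_paths <- file.path(cfg$embedding, paste0(ids, ".tsv"))
    missing <- ids[!file.exists(emb_paths)]
    if (length(missing) > 0L) {
      stop(sprintf("missing embedding file(s) for: %s",
                   paste(missing, collapse = ", ")))
    }
  }
  e <- if (needs_recm) read_energy_matrix(cfg$recm)
  groupings <- if ("QLC" %in% cfg$views) ctd_groupings()
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    parts <- list()
    if ("ESM" %in% cfg$views) {
      emb <- if (cfg$embedding == "mock") {
        mock_embed(r, D = cfg$embedding_dim, seed = cfg$seed)
      } else {
        read_embedding_matrix(file.path(cfg$embedding, paste0(r$id, ".tsv")),
                              L = nchar(r$sequence))
      }
      parts$ESM <- mean_pool(emb)
    }
    if (needs_pssm) {
      pm <- read_pssm_ascii(file.path(cfg$pssm_dir, paste0(r$id, ".pssm")),
                            sequence = r$sequence)
      parts[["PSSM-CLBP"]] <- as.numeric(pssm_clbp(pm))
    }
    if ("QLC" %in% cfg$views) parts$QLC <- as.numeric(qlc_vector(r, groupings))
    if (needs_recm) parts[["RECM-CLBP"]] <- as.numeric(recm_clbp(r, e))
    unlist(parts[cfg$views[cfg$views %in% names(parts)]], use.names = FALSE)
  })
  widths <- c(ESM = if ("ESM" %in% cfg$views) cfg$embedding_dim,
              `PSSM-CLBP` = if (needs_pssm) 236L,
              QLC = if ("QLC" %in% cfg$views) 147L,
              `RECM-CLBP` = if (needs_recm) 236L)
  labels <- NULL
  if (!is.null(cfg$labels)) {
    lab <- utils::read.delim(cfg$labels)
    labels <- lab$label[match(ids, lab$id)]
    if (anyNA(labels)) stop("labels file is missing some record ids")
  }
  feature_table(do.call(rbind, rows), ids, widths, labels)
}

# z-score normalize the QLC block in place, fitting or applying stats
.normalize_qlc <- function(table, stats = NULL) {
  if (!"QLC" %in% names(table$blocks)) return(list(table = table, stats = stats))
  ends <- cumsum(table$blocks)
  i <- match("QLC", names(table$blocks))
  cols <- (ends[i] - table$blocks[i] + 1L):ends[i]
  sub <- feature_table(table$matrix[, cols, drop = FALSE], table$ids,
                       c(QLC = length(cols)))
  if (is.null(stats)) stats <- fit_normalization(sub)
  table$matrix[, cols] <- apply_normalization(sub, stats)$matrix
  list(table = table, stats = stats)
}

#' Fit the full pipeline on a training set
#'
#' Runs feature extraction, QLC normalization (statistics fitted on the
#' training rows only), weight learning by differential evolution,
#' weighted concatenation, binary tree-growth feature selection and
#' classifier training, and packages every fitted artifact into a model
#' bundle. Stages configured as `NULL` fall back to identity (unit
#' weights / all features).
#'
#' @param cfg A [pipeline_config()] with labels.
#' @return List of class `model_bundle` with elements `norm_stats`,
#'   `weights`, `mask`, `model`, `views`, `config`.
#' @export
fit_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$labels)) stop("fitting requires a labels file")
  table <- extract_features(cfg)
  nq <- .normalize_qlc(table)
  table <- nq$table
  if (!is.null(cfg$de)) {
    integ <- de_integrate(table, cfg$de)
    w <- integ$w
    wt <- integ$table
    de_trace <- integ$de$trace
  } else {
    w <- rep(1, length(table$blocks))
    wt <- table
    de_trace <- NULL
  }
  if (!is.null(cfg$btg)) {
    sel <- btg_select(wt, cfg$btg)
    mask <- sel$mask
    btg_trace <- sel$trace
  } else {
    mask <- rep(TRUE, ncol(wt$matrix))
    btg_trace <- NULL
  }
  final <- apply_mask(wt, mask)
  model <- snbilstm_train(final, cfg$classifier)
  structure(list(norm_stats = nq$stats, weights = w, mask = mask,
                 model = model, views = cfg$views, config = cfg,
                 de_trace = de_trace, btg_trace = btg_trace,
                 schema_version = 1L),
            class = "model_bundle")
}

#' Predict with a fitted pipeline
#'
#' Applies the stored normalization statistics, view weights, feature
#' mask and trained classifier to new sequences through the same code
#' paths used at training time.
#'
#' @param bundle A `model_bundle` from [fit_pipeline()] or
#'   [load_model_bundle()].
#' @param cfg A [pipeline_config()] pointing at the inputs to score
#'   (views and embedding settings must match the training run).
#' @param threshold Optional override of the decision threshold.
#' @return Data frame with `id`, `probability`, `label`.
#' @export
predict_pipeline <- function(bundle, cfg, threshold = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!identical(cfg$views, bundle$views)) {
    stop("prediction views must match the training views")
  }
  table <- extract_features(cfg)
  table <- .normalize_qlc(table, bundle$norm_stats)$table
  wt <- weighted_concat(table, bundle$weights)
  final <- apply_mask(wt, bundle$mask)
  pred <- snbilstm_predict(bundle$model, final, threshold = threshold)
  data.frame(id = table$ids, probability = pred$probability,
             label = pred$label)
}

#' Save a model bundle to a directory
#'
#' Writes a JSON manifest (schema version, views, weights, mask indices,
#' configuration snapshot) plus binary parameter files for the fitted
#' normalization statistics and classifier.
#'
#' @param bundle A `model_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema_version = bundle$schema_version,
                   views = bundle$views,
                   weights = bundle$weights,
                   mask_indices0 = which(bundle$mask) - 1L,
                   mask_length = length(bundle$mask),
                   classifier_variant = bundle$model$config$variant,
                   threshold = bundle$model$config$threshold)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  invisible(dir)
}

#' Load a model bundle saved by [save_model_bundle()]
#'
#' @param dir Bundle directory.
#' @return The `model_bundle`.
#' @export
load_model_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  bundle_path <- file.path(dir, "bundle.rds")
  if (!file.exists(manifest_path) || !file.exists(bundle_path)) {
    stop(sprintf("not a model bundle directory: %s", dir))
  }
  manifest <- jsonlite::read_json(manifest_path)
  bundle <- readRDS(bundle_path)
  if (!identical(as.integer(manifest$schema_version),
                 as.integer(bundle$schema_version))) {
    stop("bundle manifest does not match stored parameters")
  }
  bundle
}
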