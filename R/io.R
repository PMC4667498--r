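#' Read a delimited feature-by-sample matrix as an omics block
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers. Cells that are empty or `NA` are masked as missing. Binary
#' and Poisson blocks are validated on read.
#'
#' @param path Path to the delimited text file.
#' @param type Data type of the block, see [omics_block()].
#' @param delimiter Field separator; by default inferred from the file
#'   extension (`","` for `.csv`, tab otherwise).
#' @param name Block label; defaults to the file name without extension.
#' @param transpose Set `TRUE` when the file stores samples in rows and
#'   features in columns.
#' @return An [omics_block()].
#' @export
read_omics_block <- function(path, type, delimiter = NULL, name = NULL,
                             transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))

  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, quote = "\"",
                           comment.char = "", na.strings = c("NA", ""))
  if (ncol(raw) < 2) stop("expected a feature-id column plus data columns in ",
                          path)
  fids <- raw[[1]]
  if (anyDuplicated(fids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "))
  chr <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- !is.na(chr) & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", chr[bad][1], "' in ", path, " at feature '",
         fids[idx[1]], "', sample '", colnames(chr)[idx[2]], "'")
  }
  dimnames(num) <- list(fids, colnames(chr))
  if (transpose) num <- t(num)
  omics_block(num, type, name = name)
}

#' Write an omics block as delimited text
#'
#' Masked entries are written as `NA`, so a write/read round trip reproduces
#' both the data and the mask.
#'
#' @param block An [omics_block()].
#' @param path Destination path; the delimiter is inferred from the extension
#'   unless given.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_omics_block <- function(block, path, delimiter = NULL) {
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # format at full double precision so a write/read round trip is exact
  chr <- matrix(sprintf("%.17g", block$data), nrow(block$data))
  chr[!block$mask] <- "NA"
  df <- data.frame(feature = block$feature_ids, chr, check.names = FALSE)
  colnames(df) <- c("feature", block$sample_ids)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align blocks to a shared sample set
#'
#' @param blocks List of [omics_block()] objects.
#' @param policy `"strict"` (default) errors unless all blocks carry an
#'   identical sample id set; `"intersect"` subsets and reorders every block
#'   to the sorted common sample set and reports dropped samples.
#' @return List of aligned blocks with identical, identically ordered
#'   `sample_ids`.
#' @export
align_samples <- function(blocks, policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  if (inherits(blocks, "omics_block")) blocks <- list(blocks)
  if (!length(blocks)) stop("at least one block required")
  sets <- lapply(blocks, `[[`, "sample_ids")
  common <- Reduce(intersect, sets)
  if (!length(common)) stop("blocks share no samples")
  if (policy == "strict") {
    if (!all(vapply(sets, function(s) setequal(s, common), logical(1))))
      stop("sample sets differ across blocks; use policy = 'intersect' ",
           "to take the common subset")
    ord <- sets[[1]] # keep the first block's order
  } else {
    ord <- sort(common)
    dropped <- unique(unlist(lapply(sets, setdiff, common)))
    if (length(dropped))
      message("align_samples: dropping ", length(dropped),
              " sample(s) absent from some block: ",
              paste(utils::head(dropped, 10), collapse = ", "),
              if (length(dropped) > 10) ", ..." else "")
  }
  lapply(blocks, function(b) {
    j <- match(ord, b$sample_ids)
    omics_block(b$data[, j, drop = FALSE], b$type, name = b$name,
                mask = b$mask[, j, drop = FALSE])
  })
}

#' Assemble a pipeline configuration
#'
#' @param blocks Either a list of [omics_block()] objects or a list of
#'   `list(path =, type =)` entries to be read from disk.
#' @param rank Target rank for the final fit; if `NULL`, the elbow of the
#'   rank scan is used.
#' @param ranks Candidate ranks for the explained-variation scan (`NULL`
#'   skips the scan; then `rank` is required).
#' @param ks Candidate cluster numbers for the silhouette scan.
#' @param step,tol,max_iter Solver settings, see [lra_fit()].
#' @param restarts,seed k-means settings, see [cluster_samples()].
#' @param align Sample alignment policy, see [align_samples()].
#' @param center,scale. Gaussian preprocessing flags, see [lra_fit()].
#' @param signatures Compute per-cluster differential-feature tables.
#' @param out_dir Output directory; created if needed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(blocks, rank = NULL, ranks = NULL, ks = 2:6,
                       step = 0.5, tol = 1e-6, max_iter = 100,
                       restarts = 20, seed = 1,
                       align = c("strict", "intersect"),
                       center = FALSE, scale. = FALSE,
                       signatures = TRUE, out_dir = "lromics_run") {
  align <- match.arg(align)
  if (is.null(rank) && is.null(ranks))
    stop("provide a rank, a rank scan range, or both")
  structure(list(blocks = blocks, rank = rank, ranks = ranks, ks = ks,
                 step = step, tol = tol, max_iter = max_iter,
                 restarts = restarts, seed = seed, align = align,
                 center = center, scale. = scale., signatures = signatures,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full integration workflow
#'
#' Executes read, align, (optional) rank scan, fit, dimension reduction,
#' silhouette scan over cluster numbers, and per-cluster signature tests,
#' writing every result plus the configuration, seed and package version to
#' the output directory so a run can be reproduced exactly.
#'
#' Files written: `config.json`, `rank_scan.tsv` (if scanned),
#' `fit_trace.tsv` (objective, shrinkage level and explained variation per
#' iteration), `singular_values.tsv`, `coordinates.tsv` (samples x rank),
#' `cluster_scan.tsv`, `labels.tsv`, `signatures_cluster<id>.tsv` and
#' `log.txt`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fit, reduction, rank scan, cluster scan,
#'   chosen clustering, signature tables and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf,
                                append = TRUE)
  cat(sprintf("lromics %s | R %s | seed %d | %s\n",
              as.character(utils::packageVersion("lromics")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = logf)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("ERROR in stage '", name, "': ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  cfg_json <- config
  cfg_json$blocks <- lapply(config$blocks, function(b) {
    if (inherits(b, "omics_block"))
      list(name = b$name, type = b$type, n_features = nrow(b$data),
           n_samples = ncol(b$data), source = "in-memory")
    else b
  })
  jsonlite::write_json(unclass(cfg_json),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  blocks <- stage("read", {
    lapply(config$blocks, function(b) {
      if (inherits(b, "omics_block")) b
      else read_omics_block(b$path, b$type,
                            delimiter = b$delimiter %||% NULL,
                            name = b$name %||% NULL,
                            transpose = isTRUE(b$transpose))
    })
  })
  blocks <- stage("align", align_samples(blocks, config$align))
  log_line("blocks: ", paste(vapply(blocks, function(b)
    sprintf("%s[%s %dx%d]", b$name, b$type, nrow(b$data), ncol(b$data)),
    character(1)), collapse = ", "))

  scan <- NULL
  rank <- config$rank
  if (!is.null(config$ranks)) {
    scan <- stage("rank_scan",
                  scan_rank(blocks, config$ranks, step = config$step,
                            tol = config$tol, max_iter = config$max_iter,
                            center = config$center, scale. = config$scale.))
    utils::write.table(scan, file.path(config$out_dir, "rank_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (is.null(rank)) {
      rank <- elbow_rank(scan)
      log_line("rank chosen at explained-variation elbow: ", rank)
    }
  }

  fit <- stage("fit", lra_fit(blocks, rank = rank, step = config$step,
                              tol = config$tol, max_iter = config$max_iter,
                              center = config$center, scale. = config$scale.))
  log_line(sprintf("fit: rank %d, %d iterations, converged %s, ev %.4f",
                   fit$rank, fit$n_iter, fit$converged,
                   fit$explained_variation))
  utils::write.table(
    data.frame(iteration = seq_len(fit$n_iter),
               objective = fit$objective_trace, mu = fit$mu_trace,
               explained_variation = fit$ev_trace),
    file.path(config$out_dir, "fit_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(index = seq_along(fit$singular_values),
               singular_value = fit$singular_values),
    file.path(config$out_dir, "singular_values.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  red <- stage("reduce", reduce_dims(fit))
  utils::write.table(
    data.frame(sample = red$sample_ids, t(red$coords), check.names = FALSE),
    file.path(config$out_dir, "coordinates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  cl_scan <- stage("cluster_scan",
                   scan_clusters(red, ks = config$ks,
                                 restarts = config$restarts,
                                 seed = config$seed))
  utils::write.table(cl_scan, file.path(config$out_dir, "cluster_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  best_k <- attr(cl_scan, "best_k")
  best <- attr(cl_scan, "clusterings")[[as.character(best_k)]]
  log_line(sprintf("clusters: best k = %d, silhouette %.4f", best_k,
                   best$silhouette))
  utils::write.table(
    data.frame(sample = red$sample_ids, cluster = best$labels,
               silhouette = best$per_sample_silhouette),
    file.path(config$out_dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- NULL
  if (isTRUE(config$signatures)) {
    sig <- stage("signatures", {
      lapply(sort(unique(best$labels)), function(cl) {
        tab <- signature_features(blocks, best$labels, cl)
        utils::write.table(tab, file.path(config$out_dir,
                                          paste0("signatures_cluster", cl,
                                                 ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        tab
      })
    })
  }
  log_line("done")

  invisible(list(fit = fit, reduction = red, rank_scan = scan,
                 cluster_scan = cl_scan, clustering = best,
                 signatures = sig, out_dir = config$out_dir))
}

#' Write a simulated dataset to disk
#'
#' Writes each block as TSV plus a JSON sidecar holding the simulation
#' specification and the true cluster labels.
#'
#' @param sim A [simulate_multiomics()] result.
#' @param dir Destination directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in sim$blocks)
    write_omics_block(b, file.path(dir, paste0(b$name, ".tsv")))
  sidecar <- list(
    spec = unclass(sim$spec),
    true_labels = as.list(stats::setNames(sim$labels,
                                          colnames(sim$theta))))
  jsonlite::write_json(sidecar, file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
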