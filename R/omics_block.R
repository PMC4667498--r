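#' Construct an omics data block
#'
#' An omics block is one feature-by-sample data matrix together with its
#' probabilistic data type and an observation mask. Blocks of different types
#' (e.g. copy number, somatic mutation, RNA-seq counts) over the same samples
#' are the inputs of [lra_fit()].
#'
#' @param data Numeric matrix, features in rows and samples in columns.
#'   Row names are used as feature identifiers and column names as sample
#'   identifiers; defaults are generated when absent. `NA` entries are
#'   treated as missing and masked out.
#' @param type One of `"gaussian"` (real-valued data, unit-variance normal
#'   model), `"binary"` (0/1 data, Bernoulli-logit model) or `"poisson"`
#'   (non-negative integer counts, Poisson log-link model).
#' @param name Label for the block, used in messages and output files.
#' @param mask Optional logical matrix of the same shape as `data`; `TRUE`
#'   marks an observed entry. Defaults to `!is.na(data)` and is intersected
#'   with it, so `NA` cells are always masked.
#'
#' @return An object of class `"omics_block"`: a list with elements `name`,
#'   `data`, `type`, `mask`, `feature_ids` and `sample_ids`.
#'
#' @details Masked entries contribute zero to the likelihood and zero to its
#'   gradient; this is the usual marginalization for conditionally
#'   independent observations. Binary blocks must contain only 0/1 among
#'   observed entries, Poisson blocks only non-negative integers.
#'
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' b <- omics_block(x, "gaussian", name = "methylation")
#' b
#' @export
omics_block <- function(data, type = c("gaussian", "binary", "poisson"),
                        name = "block", mask = NULL) {
  type <- match.arg(type)
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(mask)) {
    mask <- !is.na(data)
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(data)))
      stop("'mask' must be a logical matrix with the same shape as 'data'")
    mask <- mask & !is.na(data)
  }
  data[!mask] <- 0 # neutral placeholder; never read through the mask
  feature_ids <- rownames(data)
  if (is.null(feature_ids)) feature_ids <- paste0(name, "_f", seq_len(nrow(data)))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids in block '", name, "'")
  sample_ids <- colnames(data)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(data)))
  dimnames(data) <- dimnames(mask) <- list(feature_ids, sample_ids)

  obs <- data[mask]
  if (type == "binary" && length(obs) && !all(obs %in% c(0, 1)))
    stop("binary block '", name, "' has observed entries outside {0, 1}")
  if (type == "poisson" && length(obs) &&
      (any(obs < 0) || any(abs(obs - round(obs)) > 1e-8)))
    stop("poisson block '", name,
         "' has observed entries that are not non-negative integers")

  structure(
    list(name = name, data = data, type = type, mask = mask,
         feature_ids = feature_ids, sample_ids = sample_ids),
    class = "omics_block"
  )
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("omics_block '%s' (%s): %d features x %d samples, %.1f%% observed\n",
              x$name, x$type, nrow(x$data), ncol(x$data),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$data)

# Validate a list of blocks destined for one joint model: identical, identically
# ordered sample ids across blocks.
check_blocks <- function(blocks) {
  if (inherits(blocks, "omics_block")) blocks <- list(blocks)
  if (!length(blocks)) stop("at least one omics block is required")
  if (!all(vapply(blocks, inherits, logical(1), "omics_block")))
    stop("all elements must be omics_block objects")
  sids <- blocks[[1]]$sample_ids
  for (b in blocks[-1]) {
    if (!identical(b$sample_ids, sids))
      stop("blocks do not share an identical, identically ordered sample set; ",
           "see align_samples()")
  }
  blocks
}

# Row offsets of each block inside the stacked parameter matrix.
block_offsets <- function(blocks) {
  p <- vapply(blocks, function(b) nrow(b$data), integer(1))
  ends <- cumsum(p)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

#' Dummy-code a categorical matrix into a binary omics block
#'
#' Expands each categorical feature into one indicator row per level
#' (full one-hot, no reference level dropped, so levels stay symmetric under
#' the low-rank prior). The resulting block uses the Bernoulli model.
#'
#' @param x Matrix (character or factor-coded) of level labels, features in
#'   rows, samples in columns. `NA` entries are treated as missing.
#' @param levels Character vector of admissible levels. Defaults to the
#'   sorted unique observed values.
#' @param name Block label.
#'
#' @return A binary [omics_block()] with one row per (feature, level) pair,
#'   named `"<feature>:<level>"`. A missing input entry masks all derived
#'   rows for that feature/sample.
#'
#' @examples
#' m <- matrix(c("A", "B", "A"), 1, 3,
#'             dimnames = list("site1", paste0("s", 1:3)))
#' dummy_encode(m, levels = c("A", "B"))
#' @export
dummy_encode <- function(x, levels = NULL, name = "categorical") {
  if (!is.matrix(x)) x <- as.matrix(x)
  dn <- dimnames(x)
  x <- matrix(as.character(x), nrow(x), ncol(x), dimnames = dn)
  if (is.null(levels)) levels <- sort(unique(stats::na.omit(as.vector(x))))
  obs <- !is.na(x)
  bad <- obs & !(x %in% levels)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("entry '", x[bad][1], "' at feature ", idx[1], ", sample ", idx[2],
         " is not among the declared levels")
  }
  fids <- rownames(x)
  if (is.null(fids)) fids <- paste0("f", seq_len(nrow(x)))
  sids <- colnames(x)
  if (is.null(sids)) sids <- paste0("s", seq_len(ncol(x)))

  out <- matrix(0, nrow(x) * length(levels), ncol(x))
  msk <- matrix(FALSE, nrow(out), ncol(out))
  rn <- character(nrow(out))
  r <- 0L
  for (i in seq_len(nrow(x))) {
    for (lv in levels) {
      r <- r + 1L
      out[r, ] <- as.numeric(x[i, ] == lv)
      msk[r, ] <- obs[i, ]
      rn[r] <- paste0(fids[i], ":", lv)
    }
  }
  out[!msk] <- 0
  dimnames(out) <- dimnames(msk) <- list(rn, sids)
  omics_block(out, "binary", name = name, mask = msk)
}
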