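#' Mask-based feature imputation
#'
#' Replaces unobserved entries by a type-specific fallback vector:
#' `out = m * x + (1 - m) * b` with the fallback broadcast row-wise. Observed
#' entries are returned bit-identical.
#'
#' @param x numeric feature matrix.
#' @param mask matrix of the same shape with entries in `{0, 1}` (1 =
#'   observed).
#' @param fallback numeric vector of length `ncol(x)`.
#' @return The imputed matrix.
#' @examples
#' impute_features(matrix(c(1, 2), 1), matrix(c(1, 0), 1), c(9, 9))
#' @export
impute_features <- function(x, mask, fallback) {
  stopifnot(is.matrix(x), all(dim(x) == dim(mask)),
            length(fallback) == ncol(x))
  if (!all(mask %in% c(0, 1))) {
    stop("mask entries must be 0 or 1")
  }
  b <- matrix(fallback, nrow(x), ncol(x), byrow = TRUE)
  out <- mask * x + (1 - mask) * b
  dimnames(out) <- dimnames(x)
  out
}

#' Column-wise mean of observed entries
#'
#' The fallback vector for [impute_features()]: per-column mean over entries
#' with mask 1. Columns with no observed entry fall back to 0 with a warning.
#'
#' @inheritParams impute_features
#' @return Numeric vector of length `ncol(x)`.
#' @export
mean_fallback <- function(x, mask) {
  stopifnot(is.matrix(x), all(dim(x) == dim(mask)))
  obs <- colSums(mask)
  out <- colSums(x * mask) / pmax(obs, 1)
  if (any(obs == 0)) {
    warning(sum(obs == 0), " fully missing column(s); fallback set to 0")
    out[obs == 0] <- 0
  }
  out
}

#' Per-type z-score normalisation
#'
#' Standardises each continuous type's columns to mean 0 and population
#' (1/N) standard deviation 1, computed over that type's nodes only.
#' Constant columns map to 0. Binary-flagged types (fingerprints, membership
#' encodings) pass through unchanged to preserve bit semantics. Calling this
#' before imputation (any mask zeros) is an error.
#'
#' @param features a `node_feature_set` (see [generate_node_features()]).
#' @return The feature set with standardised continuous matrices.
#' @export
zscore_by_type <- function(features) {
  stopifnot(inherits(features, "node_feature_set"))
  for (type in names(features)) {
    ft <- features[[type]]
    if (any(ft$mask == 0)) {
      stop("zscore_by_type called before imputation: type '", type,
           "' still has missing entries")
    }
    if (isTRUE(ft$binary)) next
    mu <- colMeans(ft$x)
    sd_pop <- sqrt(colMeans(sweep(ft$x, 2L, mu)^2))
    z <- sweep(ft$x, 2L, mu)
    nonconst <- sd_pop > 0
    z[, nonconst] <- sweep(z[, nonconst, drop = FALSE], 2L,
                           sd_pop[nonconst], "/")
    z[, !nonconst] <- 0
    features[[type]]$x <- z
  }
  features
}

# Impute every type with its column-mean fallback, then z-score continuous
# types. The standard preprocessing entry point.
#' Impute and standardise a node feature set
#'
#' Applies [mean_fallback()] + [impute_features()] per type, then
#' [zscore_by_type()].
#'
#' @inheritParams zscore_by_type
#' @return The preprocessed `node_feature_set` (all masks 1 afterwards).
#' @export
preprocess_features <- function(features) {
  stopifnot(inherits(features, "node_feature_set"))
  for (type in names(features)) {
    ft <- features[[type]]
    if (any(ft$mask == 0)) {
      fb <- mean_fallback(ft$x, ft$mask)
      features[[type]]$x <- impute_features(ft$x, ft$mask, fb)
      features[[type]]$mask[] <- 1
    }
  }
  zscore_by_type(features)
}

#' Project a raw feature vector into the shared latent space
#'
#' Type-specific affine map `h = W_t x + b_t` taking heterogeneous raw
#' features to a common dimension `d` so all node types can exchange
#' messages. The projection weights live in the model parameter container and
#' are trained end-to-end with the encoder.
#'
#' @param x_row numeric vector of raw features.
#' @param node_type the node's type (names the projection used).
#' @param params a `hetgnn_params` object (see [hetgnn_params()]).
#' @return Numeric vector of length `d`.
#' @export
project_to_shared_space <- function(x_row, node_type, params) {
  w_name <- paste0("proj_W_", node_type)
  b_name <- paste0("proj_b_", node_type)
  if (is.null(params$values[[w_name]])) {
    stop("no projection parameters for node type '", node_type, "'")
  }
  W <- params$values[[w_name]]
  if (ncol(W) != length(x_row)) {
    stop(sprintf("projection shape mismatch for node type '%s': W is %dx%d, x has length %d",
                 node_type, nrow(W), ncol(W), length(x_row)))
  }
  as.numeric(W %*% x_row) + as.numeric(params$values[[b_name]])
}

#' Cosine-similarity edges from an omics matrix
#'
#' Emits every pair of row profiles whose cosine similarity reaches the
#' threshold; the auxiliary similarity network that molecular profiles induce
#' on top of curated relations. Zero-norm rows are never matched.
#'
#' @param omics numeric matrix, one row per entity.
#' @param threshold cosine threshold in `[-1, 1]`.
#' @return data.frame with columns `i`, `j` (row indices, `i < j`) and
#'   `similarity`.
#' @export
omics_similarity_edges <- function(omics, threshold) {
  stopifnot(is.matrix(omics), threshold >= -1, threshold <= 1)
  if (nrow(omics) < 2L) {
    return(data.frame(i = integer(), j = integer(), similarity = numeric()))
  }
  nrm <- sqrt(rowSums(omics^2))
  ok <- nrm > 0
  sim <- tcrossprod(omics / ifelse(nrm > 0, nrm, 1))
  sim[!ok, ] <- -Inf
  sim[, !ok] <- -Inf
  sim[lower.tri(sim, diag = TRUE)] <- -Inf
  hits <- which(sim >= threshold, arr.ind = TRUE)
  data.frame(i = as.integer(hits[, 1]), j = as.integer(hits[, 2]),
             similarity = sim[hits])
}
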