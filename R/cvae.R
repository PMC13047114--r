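# Disease-conditioned variational autoencoder over drug-pair embeddings.
#
# The encoder sees an order-invariant pooling of the two drug embeddings
# ([h1 + h2 || |h1 - h2| || h_s]) and emits a diagonal Gaussian over a
# 64-dimensional latent; the decoder maps [z || h_s] back to two drug
# embeddings through a shared trunk with two heads. Synergy of a decoded pair
# is the sigmoid of their inner product.

#' Initialise CVAE parameters
#'
#' Encoder and decoder are each two fully connected layers of 128 hidden
#' units with ReLU activations; the encoder ends in linear mean and
#' log-variance heads over a 64-dimensional latent space.
#'
#' @param d embedding dimension of drugs/diseases (input space).
#' @param latent_dim latent dimension (default 64).
#' @param hidden hidden width (default 128).
#' @param kl_weight weight of the KL term in the training loss (default 1).
#' @param seed integer seed for initialisation.
#' @return An object of class `cvae_params`.
#' @export
cvae_params <- function(d, latent_dim = 64L, hidden = 128L, kl_weight = 1,
                        seed = 1L) {
  d <- as.integer(d)
  latent_dim <- as.integer(latent_dim)
  hidden <- as.integer(hidden)
  with_seed(derive_seed(seed, "cvae"), {
    values <- list(
      enc_W1 = glorot(3L * d, hidden), enc_b1 = matrix(0, 1L, hidden),
      enc_W2 = glorot(hidden, hidden), enc_b2 = matrix(0, 1L, hidden),
      enc_Wmu = glorot(hidden, latent_dim),
      enc_bmu = matrix(0, 1L, latent_dim),
      enc_Wlv = glorot(hidden, latent_dim),
      enc_blv = matrix(0, 1L, latent_dim),
      dec_W1 = glorot(latent_dim + d, hidden),
      dec_b1 = matrix(0, 1L, hidden),
      dec_W2 = glorot(hidden, hidden), dec_b2 = matrix(0, 1L, hidden),
      dec_Wd1 = glorot(hidden, d), dec_bd1 = matrix(0, 1L, d),
      dec_Wd2 = glorot(hidden, d), dec_bd2 = matrix(0, 1L, d)
    )
    structure(list(values = values,
                   meta = list(d = d, latent_dim = latent_dim,
                               hidden = hidden, kl_weight = kl_weight)),
              class = "cvae_params")
  })
}

pair_pool <- function(h_d1, h_d2, h_s) {
  c(h_d1 + h_d2, abs(h_d1 - h_d2), h_s)
}

mlp2 <- function(x_row, W1, b1, W2, b2) {
  h <- pmax(as.numeric(x_row %*% W1) + as.numeric(b1), 0)
  pmax(as.numeric(h %*% W2) + as.numeric(b2), 0)
}

#' Encode a disease-conditioned drug pair
#'
#' The pair representation is order-invariant (sum and absolute difference of
#' the two drug embeddings, concatenated with the disease embedding), so
#' swapping the drugs yields bit-identical output. Returns the mean and
#' (strictly positive) standard deviation of the latent Gaussian, with
#' `sigma = exp(logvar / 2)`.
#'
#' @param h_d1,h_d2 drug embedding vectors (length `d`).
#' @param h_s disease embedding vector (length `d`).
#' @param params a [cvae_params()] object.
#' @return List with `mu` and `sigma`, each of length `latent_dim`.
#' @export
encode_pair <- function(h_d1, h_d2, h_s, params) {
  stopifnot(inherits(params, "cvae_params"))
  d <- params$meta$d
  if (length(h_d1) != d || length(h_d2) != d || length(h_s) != d) {
    stop("embedding length mismatch: expected ", d)
  }
  v <- params$values
  trunk <- mlp2(matrix(pair_pool(h_d1, h_d2, h_s), 1L),
                v$enc_W1, v$enc_b1, v$enc_W2, v$enc_b2)
  mu <- as.numeric(trunk %*% v$enc_Wmu) + as.numeric(v$enc_bmu)
  logvar <- as.numeric(trunk %*% v$enc_Wlv) + as.numeric(v$enc_blv)
  list(mu = mu, sigma = exp(logvar / 2))
}

#' Reparameterised latent sample
#'
#' `z = mu + sigma * eps` with `eps` standard normal drawn from the seeded
#' stream; `sigma = 0` collapses to `z = mu`.
#'
#' @param mu,sigma numeric vectors of equal length; `sigma >= 0`.
#' @param seed integer seed.
#' @return Numeric vector `z`.
#' @export
reparameterize_sample <- function(mu, sigma, seed) {
  stopifnot(length(mu) == length(sigma), all(sigma >= 0))
  eps <- with_seed(derive_seed(seed, "reparam"),
                   stats::rnorm(length(mu)))
  mu + sigma * eps
}

#' Decode a latent into a disease-conditioned drug pair
#'
#' Deterministic decoder: `[z || h_s]` runs through the shared trunk, and two
#' linear heads emit the pair of drug embeddings.
#'
#' @param z latent vector of length `latent_dim`.
#' @param h_s disease embedding of length `d`.
#' @param params a [cvae_params()] object.
#' @return List with `h_d1` and `h_d2`, each of length `d`.
#' @export
decode_pair <- function(z, h_s, params) {
  stopifnot(inherits(params, "cvae_params"))
  if (length(z) != params$meta$latent_dim) {
    stop("latent length mismatch: expected ", params$meta$latent_dim)
  }
  if (length(h_s) != params$meta$d) {
    stop("disease embedding length mismatch: expected ", params$meta$d)
  }
  v <- params$values
  trunk <- mlp2(matrix(c(z, h_s), 1L), v$dec_W1, v$dec_b1, v$dec_W2,
                v$dec_b2)
  list(h_d1 = as.numeric(trunk %*% v$dec_Wd1) + as.numeric(v$dec_bd1),
       h_d2 = as.numeric(trunk %*% v$dec_Wd2) + as.numeric(v$dec_bd2))
}

#' Synergy score of a drug pair
#'
#' Sigmoid of the inner product of the two (decoded) drug embeddings;
#' symmetric in its arguments.
#'
#' @param h_d1,h_d2 numeric vectors of equal length.
#' @return Scalar in `(0, 1)`.
#' @export
synergy_score <- function(h_d1, h_d2) {
  stopifnot(length(h_d1) == length(h_d2))
  sigmoid(sum(h_d1 * h_d2))
}

#' CVAE training loss
#'
#' Reconstruction is the mean squared error between the input pair embeddings
#' and the decoded pair; the KL term is the closed-form divergence of the
#' diagonal Gaussian from the standard normal,
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`, which is nonnegative and
#' zero exactly at `mu = 0, sigma = 1`.
#'
#' @param inputs numeric vector/matrix of target pair embeddings.
#' @param reconstructions decoded pair embeddings, same shape.
#' @param mu,sigma latent Gaussian parameters (vectors, or matrices with one
#'   row per pair).
#' @param kl_weight weight on the KL term.
#' @return List with `total`, `reconstruction` and `kl`.
#' @export
cvae_loss <- function(inputs, reconstructions, mu, sigma, kl_weight = 1) {
  stopifnot(length(inputs) == length(reconstructions),
            length(mu) == length(sigma))
  reconstruction <- mean((as.numeric(inputs) -
                            as.numeric(reconstructions))^2)
  mu <- as_matrix(mu)
  sigma <- as_matrix(sigma)
  if (ncol(mu) == 1L && nrow(mu) > 1L) {
    mu <- t(mu)
    sigma <- t(sigma)
  }
  kl_per <- 0.5 * rowSums(mu^2 + sigma^2 - 1 - 2 * log(sigma))
  kl <- mean(kl_per)
  list(total = reconstruction + kl_weight * kl,
       reconstruction = reconstruction, kl = kl)
}

# Batched tape loss used for training: H1, H2, HS are n x d constant inputs.
#' @keywords internal
cvae_loss_and_grads <- function(params, H1, H2, HS, seed) {
  v <- params$values
  eps <- with_seed(derive_seed(seed, "cvae_eps"), {
    matrix(stats::rnorm(nrow(H1) * params$meta$latent_dim),
           nrow(H1), params$meta$latent_dim)
  })
  tape <- ad_tape()
  leaves <- ad_wrap_params(tape, v)
  enc_in <- ad_const(tape, cbind(H1 + H2, abs(H1 - H2), HS))
  t1 <- ad_relu(tape, ad_add_bias(tape,
                                  ad_matmul(tape, enc_in, leaves$enc_W1),
                                  leaves$enc_b1))
  t2 <- ad_relu(tape, ad_add_bias(tape,
                                  ad_matmul(tape, t1, leaves$enc_W2),
                                  leaves$enc_b2))
  mu <- ad_add_bias(tape, ad_matmul(tape, t2, leaves$enc_Wmu),
                    leaves$enc_bmu)
  lv <- ad_add_bias(tape, ad_matmul(tape, t2, leaves$enc_Wlv),
                    leaves$enc_blv)
  sig <- ad_exp(tape, ad_scale(tape, lv, 0.5))
  z <- ad_add(tape, mu, ad_mul(tape, sig, ad_const(tape, eps)))
  dec_in <- ad_concat_cols(tape, list(z, ad_const(tape, HS)))
  u1 <- ad_relu(tape, ad_add_bias(tape,
                                  ad_matmul(tape, dec_in, leaves$dec_W1),
                                  leaves$dec_b1))
  u2 <- ad_relu(tape, ad_add_bias(tape,
                                  ad_matmul(tape, u1, leaves$dec_W2),
                                  leaves$dec_b2))
  R1 <- ad_add_bias(tape, ad_matmul(tape, u2, leaves$dec_Wd1),
                    leaves$dec_bd1)
  R2 <- ad_add_bias(tape, ad_matmul(tape, u2, leaves$dec_Wd2),
                    leaves$dec_bd2)
  recon <- ad_scale(tape, ad_add(tape,
                                 ad_mse(tape, R1, H1),
                                 ad_mse(tape, R2, H2)), 0.5)
  sig2 <- ad_exp(tape, lv)
  kl_terms <- ad_sub(tape,
                     ad_add(tape, ad_square(tape, mu), sig2),
                     ad_add_bias(tape, lv,
                                 ad_const(tape,
                                          matrix(1, 1L,
                                                 params$meta$latent_dim))))
  kl <- ad_scale(tape, ad_mean(tape, ad_rowsums(tape, kl_terms)), 0.5)
  # note ad_mean over the n x 1 rowsums averages per pair
  total <- ad_add(tape, recon,
                  ad_scale(tape, kl, params$meta$kl_weight))
  ad_backward(tape, total)
  list(loss = as.numeric(total$value),
       reconstruction = as.numeric(recon$value) ,
       kl = as.numeric(kl$value),
       grads = ad_collect_grads(leaves, v))
}

#' Build synergy training pairs from a knowledge graph
#'
#' Positive drug pairs are drugs sharing at least one target gene, each
#' conditioned on a disease associated (through gene-disease edges) with one
#' of the shared genes; pairs without such a disease are dropped.
#'
#' @param graph a [hetero_graph()] with `drug_targets_gene` and
#'   `gene_associates_disease` edges.
#' @param max_pairs cap on returned pairs (seeded subsample when exceeded).
#' @param seed integer seed.
#' @return data.frame with columns `drug_a`, `drug_b`, `disease_id`.
#' @export
synergy_training_pairs <- function(graph, max_pairs = 500L, seed = 1L) {
  dt <- graph$edges[graph$edges$relation == "drug_targets_gene", ]
  ga <- graph$edges[graph$edges$relation == "gene_associates_disease", ]
  targets <- split(dt$target, dt$source)
  gene_dis <- split(ga$target, ga$source)
  drugs <- names(targets)
  out <- list()
  for (i in seq_along(drugs)) {
    for (j in seq_len(i - 1L)) {
      shared <- intersect(targets[[drugs[i]]], targets[[drugs[j]]])
      if (!length(shared)) next
      dis <- unique(unlist(gene_dis[shared], use.names = FALSE))
      if (!length(dis)) next
      out[[length(out) + 1L]] <- data.frame(
        drug_a = drugs[j], drug_b = drugs[i], disease_id = dis[1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(drug_a = character(), drug_b = character(),
                      disease_id = character()))
  }
  pairs <- do.call(rbind, out)
  if (nrow(pairs) > max_pairs) {
    keep <- with_seed(derive_seed(seed, "synpairs"),
                      sample.int(nrow(pairs), max_pairs))
    pairs <- pairs[keep, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Train the CVAE on embedded drug pairs
#'
#' Adam on the weighted reconstruction + KL objective with fresh latent noise
#' each step.
#'
#' @param params a [cvae_params()] object.
#' @param pairs data.frame from [synergy_training_pairs()].
#' @param embeddings node embedding matrix (rows named by id) covering every
#'   drug and disease in `pairs`.
#' @param steps optimisation steps (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed.
#' @return List with `params` (trained), `history` (per-step total loss) and
#'   `final` (last step's loss components).
#' @export
train_cvae <- function(params, pairs, embeddings, steps = 200L, lr = 1e-3,
                       seed = 1L) {
  stopifnot(inherits(params, "cvae_params"), nrow(pairs) >= 1)
  H1 <- embeddings[pairs$drug_a, , drop = FALSE]
  H2 <- embeddings[pairs$drug_b, , drop = FALSE]
  HS <- embeddings[pairs$disease_id, , drop = FALSE]
  state <- adam_init(params$values, lr = lr)
  history <- numeric(steps)
  final <- NULL
  for (s in seq_len(steps)) {
    res <- cvae_loss_and_grads(params, H1, H2, HS,
                               seed = derive_seed(seed, paste0("step", s)))
    upd <- adam_step(params$values, res$grads, state)
    params$values <- upd$params
    state <- upd$state
    history[s] <- res$loss
    final <- res
  }
  list(params = params,
       history = history,
       final = list(total = final$loss,
                    reconstruction = final$reconstruction, kl = final$kl))
}

# Reconstruction MSE of the model on given pairs with noise-free latents
# (z = mu), used to compare trained vs untrained models.
#' @keywords internal
cvae_reconstruction_mse <- function(params, pairs, embeddings) {
  err <- 0
  for (i in seq_len(nrow(pairs))) {
    h1 <- embeddings[pairs$drug_a[i], ]
    h2 <- embeddings[pairs$drug_b[i], ]
    hs <- embeddings[pairs$disease_id[i], ]
    enc <- encode_pair(h1, h2, hs, params)
    dec <- decode_pair(enc$mu, hs, params)
    err <- err + mean((c(dec$h_d1, dec$h_d2) - c(h1, h2))^2)
  }
  err / nrow(pairs)
}

#' Generate candidate drug combinations for a disease
#'
#' Samples latents from the prior, decodes them conditioned on the disease
#' embedding, maps each decoded embedding to its cosine-nearest library drug,
#' removes self-pairs and duplicate unordered pairs (keeping the
#' highest-scoring instance), and returns pairs ranked by synergy score.
#'
#' @param disease_id disease node id (must be a row of `embeddings`).
#' @param n_samples number of latent samples.
#' @param params a trained [cvae_params()].
#' @param drug_library character vector of candidate drug ids.
#' @param embeddings node embedding matrix, rows named by id.
#' @param seed integer seed.
#' @return data.frame with columns `disease_id`, `drug_a`, `drug_b`,
#'   `synergy`, sorted by descending synergy.
#' @export
generate_combinations <- function(disease_id, n_samples, params,
                                  drug_library, embeddings, seed = 1L) {
  stopifnot(inherits(params, "cvae_params"), n_samples >= 1)
  if (length(drug_library) == 0L) stop("empty drug library")
  h_s <- embeddings[disease_id, ]
  lib <- embeddings[drug_library, , drop = FALSE]
  lib_norm <- lib / pmax(sqrt(rowSums(lib^2)), 1e-12)
  zs <- with_seed(derive_seed(seed, "gen"), {
    matrix(stats::rnorm(n_samples * params$meta$latent_dim),
           n_samples, params$meta$latent_dim)
  })
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    dec <- decode_pair(zs[i, ], h_s, params)
    nn <- function(h) {
      hn <- h / max(sqrt(sum(h^2)), 1e-12)
      drug_library[which.max(as.numeric(lib_norm %*% hn))]
    }
    a <- nn(dec$h_d1)
    b <- nn(dec$h_d2)
    if (a == b) next
    pair <- sort(c(a, b))
    rows[[i]] <- data.frame(disease_id = disease_id, drug_a = pair[1],
                            drug_b = pair[2],
                            synergy = synergy_score(dec$h_d1, dec$h_d2),
                            stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(disease_id = character(), drug_a = character(),
                      drug_b = character(), synergy = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$synergy, out$drug_a, out$drug_b), ]
  out <- out[!duplicated(paste(out$drug_a, out$drug_b, sep = "\r")), ]
  rownames(out) <- NULL
  out
}
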