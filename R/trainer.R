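# Two-stage optimization: pretraining on the VGAE loss alone, then
# fine-tuning on lambda1*L_VGAE + lambda2*L_DEC + lambda3*L_Tri with the
# DEC target refreshed every 20 epochs and MNN anchors every 500 epochs.

#' Training configuration
#'
#' @param lambda1,lambda2,lambda3 weights of the VGAE, DEC and triplet
#'   losses (default 1 each).
#' @param lr Adam learning rate (default 5e-4).
#' @param weight_decay Adam L2 weight decay (default 1e-4).
#' @param epochs_pretrain,epochs_finetune full-batch epochs of the two
#'   stages (defaults 500 and 1000, so the anchor cadence fires twice).
#' @param dec_refresh target-distribution refresh interval in epochs
#'   (default 20).
#' @param anchor_refresh MNN anchor refresh interval in epochs
#'   (default 500).
#' @param seed root seed; masking, noise draws, k-means and negative
#'   sampling all derive sub-seeds from it.
#' @param gamma scaling factor of the cosine reconstruction loss
#'   (default 2).
#' @param kl_weight weight of the KL term inside the VGAE loss; `NULL`
#'   (default) uses `1/n` as in the reference variational graph
#'   autoencoder implementation, which keeps the prior from collapsing
#'   the embedding. Set 1 for the literal unweighted sum.
#' @param mask_rate spot mask rate rho (default 0.2).
#' @param mask_resample_each_epoch resample the masked set every epoch
#'   (default FALSE: one mask per run).
#' @param J number of DEC centroids (default 20).
#' @param alpha triplet aggregation size (default 2).
#' @param tau triplet margin (default 1.0).
#' @param nn_size MNN neighborhood size (default 50).
#' @param fc_dims,gcn_hidden encoder dimensions (defaults `c(64, 16)`, 64).
#' @param relu_logvar,reparam_mode see [vgae_init()].
#' @return a `training_config` list.
#' @export
training_config <- function(lambda1 = 1, lambda2 = 1, lambda3 = 1,
                            lr = 5e-4, weight_decay = 1e-4,
                            epochs_pretrain = 500, epochs_finetune = 1000,
                            dec_refresh = 20, anchor_refresh = 500,
                            seed = 1L, gamma = 2, kl_weight = NULL,
                            mask_rate = 0.2,
                            mask_resample_each_epoch = FALSE,
                            J = 20, alpha = 2, tau = 1.0, nn_size = 50,
                            fc_dims = c(64, 16), gcn_hidden = 64,
                            relu_logvar = TRUE,
                            reparam_mode = "standard") {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0,
            dec_refresh >= 1, anchor_refresh >= 1)
  structure(as.list(environment()), class = "training_config")
}

#' Weighted overall loss
#'
#' @param lv,ld,lt VGAE, DEC and triplet loss values.
#' @param config a [training_config()].
#' @return `lambda1*lv + lambda2*ld + lambda3*lt`.
#' @export
overall_loss <- function(lv, ld, lt, config) {
  config$lambda1 * lv + config$lambda2 * ld + config$lambda3 * lt
}

# Draw the per-epoch Gaussian noise matrix from a documented sub-seed.
draw_eps <- function(n, d, root_seed, epoch, stage) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(root_seed, paste0("eps-", stage, "-", epoch)))
  matrix(stats::rnorm(n * d), n, d)
}

# Shared epoch step for both stages; `epoch` is the global epoch counter
# (fine-tuning continues pretraining's numbering so that a run with
# lambda2 = lambda3 = 0 reproduces continued pretraining exactly).
# `dec_state`/`trip_state` are NULL during pretraining.
train_epoch <- function(state, dataset, config, epoch, stage = "train",
                        dec_state = NULL, trip_state = NULL) {
  n <- dataset$n
  if (isTRUE(config$mask_resample_each_epoch))
    state$mask <- sample_mask(n, config$mask_rate,
                              seed = derive_seed(config$seed,
                                                 paste0("mask-", epoch)))
  eps <- draw_eps(n, state$model$d, config$seed, epoch, stage)
  X_mask <- apply_mask(dataset$X, state$mask, state$model$params$mask_vec)
  fw <- vgae_forward(state$model, X_mask, dataset$A_hat,
                     training = TRUE, eps = eps)
  state$model <- fw$model
  cache <- fw$cache

  At <- decode_adjacency(cache$Z)
  lg <- mean((state$A_dense - At)^2)
  lkl <- loss_kl(cache$mu, cache$logvar)
  lsce <- if (length(state$mask$V_m) > 0)
    loss_sce(dataset$X, cache$Xt, state$mask$V_m, config$gamma) else 0
  klw <- config$kl_weight %||% (1 / n)
  lv <- loss_vgae(lg, klw * lkl, lsce)

  ld <- 0; lt <- 0
  dZ_extra <- NULL
  dC <- NULL
  if (!is.null(dec_state) && config$lambda2 > 0) {
    # per-spot mean, so every loss component is averaged over its own
    # support and the lambda weights are size-independent
    dg <- dec_gradients(cache$Z, state$centroids, dec_state$P)
    ld <- loss_dec(dec_state$P, dg$Q) / n
    dZ_extra <- config$lambda2 * dg$dZ / n
    dC <- config$lambda2 * dg$dC / n
  }
  if (!is.null(trip_state) && config$lambda3 > 0) {
    tg <- triplet_loss_grad(cache$Z, trip_state, tau = config$tau)
    lt <- tg$loss
    dZ_extra <- if (is.null(dZ_extra)) config$lambda3 * tg$dZ
                else dZ_extra + config$lambda3 * tg$dZ
  }

  total <- overall_loss(lv, ld, lt, config)
  if (!is.finite(total))
    stop(sprintf(
      "non-finite loss at %s epoch %d (graph=%.4g kl=%.4g sce=%.4g dec=%.4g tri=%.4g)",
      stage, epoch, lg, lkl, lsce, ld, lt), call. = FALSE)

  grads <- vgae_backward(state$model, cache, state$A_dense, dataset$X,
                         state$mask$V_m, gamma = config$gamma,
                         lambda1 = config$lambda1, dZ_extra = dZ_extra,
                         kl_weight = klw)
  if (!is.null(dC)) grads$centroids <- dC

  params <- state$model$params
  if (!is.null(state$centroids)) params$centroids <- state$centroids
  st <- adam_step(state$opt, params, grads)
  state$opt <- st$opt
  if (!is.null(state$centroids)) {
    state$centroids <- st$params$centroids
    st$params$centroids <- NULL
  }
  state$model$params <- st$params
  state$losses <- c(graph = lg, kl = lkl, sce = lsce, dec = ld,
                    tri = lt, total = total)
  state
}

new_train_state <- function(dataset, config) {
  model <- vgae_init(dataset$m, fc_dims = config$fc_dims,
                     gcn_hidden = config$gcn_hidden,
                     seed = derive_seed(config$seed, "init"),
                     relu_logvar = config$relu_logvar,
                     reparam_mode = config$reparam_mode)
  mask <- sample_mask(dataset$n, config$mask_rate,
                      seed = derive_seed(config$seed, "mask"))
  opt <- adam_new(model$params, lr = config$lr,
                  weight_decay = config$weight_decay)
  list(model = model, mask = mask, opt = opt,
       A_dense = as.matrix(dataset$A), centroids = NULL)
}

# Extract the embedding with eps = 0 (posterior mean) and normalization
# layers in inference mode, from the unmasked input.
extract_embedding <- function(state, dataset) {
  vgae_encode(dataset$X, dataset$A_hat, state$model,
              training = FALSE, eps = 0)
}

#' Pretrain the masked VGAE
#'
#' Full-batch optimization of `L_VGAE = L_graph + L_KL + L_sce` for
#' `config$epochs_pretrain` epochs.
#'
#' @param dataset a `joint_dataset` from [build_joint_dataset()].
#' @param config a [training_config()].
#' @param log_file optional TSV path receiving per-epoch loss components.
#' @return list of class `pretrain_result`: `embedding`
#'   (a `latent_embedding`), `state` (model + optimizer, input to
#'   [finetune()]), `history` (loss matrix).
#' @export
pretrain <- function(dataset, config, log_file = NULL) {
  state <- new_train_state(dataset, config)
  history <- matrix(NA_real_, nrow = config$epochs_pretrain, ncol = 6,
                    dimnames = list(NULL, c("graph", "kl", "sce", "dec",
                                            "tri", "total")))
  for (e in seq_len(config$epochs_pretrain)) {
    state <- train_epoch(state, dataset, config, e)
    history[e, ] <- state$losses
  }
  if (!is.null(log_file))
    utils::write.table(cbind(epoch = seq_len(nrow(history)), history),
                       log_file, sep = "\t", row.names = FALSE, quote = FALSE)
  structure(list(embedding = extract_embedding(state, dataset),
                 state = state, history = history, config = config),
            class = "pretrain_result")
}

#' Fine-tune with DEC refinement and triplet batch correction
#'
#' Initializes DEC centroids by k-means on the pretrained embedding, then
#' optimizes `lambda1*L_VGAE + lambda2*L_DEC + lambda3*L_Tri` for
#' `config$epochs_finetune` epochs. The DEC target distribution is
#' recomputed every `dec_refresh` epochs; MNN anchors and negative draws
#' every `anchor_refresh` epochs (and at epoch 1). Gradients never flow
#' through the target distribution.
#'
#' @param dataset a `joint_dataset`.
#' @param pretrained a `pretrain_result` from [pretrain()].
#' @param config a [training_config()]; pass the same object used for
#'   pretraining for a coherent seed path.
#' @param log_file optional TSV path for per-epoch loss components.
#' @return list of class `finetune_result`: `embedding`, `state`,
#'   `history`, `centroids`, `Q`.
#' @export
finetune <- function(dataset, pretrained, config, log_file = NULL) {
  state <- pretrained$state
  use_dec <- config$lambda2 > 0
  use_tri <- config$lambda3 > 0 && length(unique(dataset$slice_of)) > 1
  dec_state <- NULL
  trip_state <- NULL

  if (use_dec) {
    Z0 <- pretrained$embedding$Z
    state$centroids <- init_centroids(Z0, J = min(config$J, dataset$n),
                                      seed = derive_seed(config$seed, "dec"))
    # optimizer slots for the new centroid parameter
    state$opt$m$centroids <- state$centroids * 0
    state$opt$v$centroids <- state$centroids * 0
  }

  history <- matrix(NA_real_, nrow = config$epochs_finetune, ncol = 6,
                    dimnames = list(NULL, c("graph", "kl", "sce", "dec",
                                            "tri", "total")))
  for (e in seq_len(config$epochs_finetune)) {
    if (use_dec && ((e - 1) %% config$dec_refresh == 0)) {
      emb <- extract_embedding(state, dataset)
      Q <- soft_assign(emb$Z, state$centroids)
      dec_state <- list(P = target_distribution(Q))
    }
    if (use_tri && ((e - 1) %% config$anchor_refresh == 0)) {
      emb <- extract_embedding(state, dataset)
      trip_state <- build_triplet_structure(
        emb$Z, dataset$slice_of, dataset$A,
        nn_size = config$nn_size, alpha = config$alpha,
        seed = derive_seed(config$seed, paste0("neg", e)))
      if (is.null(trip_state))
        warning("no MNN anchors found; triplet term contributes 0")
    }
    state <- train_epoch(state, dataset, config, config$epochs_pretrain + e,
                         dec_state = dec_state, trip_state = trip_state)
    history[e, ] <- state$losses
  }
  if (!is.null(log_file))
    utils::write.table(cbind(epoch = seq_len(nrow(history)), history),
                       log_file, sep = "\t", row.names = FALSE, quote = FALSE)
  emb <- extract_embedding(state, dataset)
  structure(list(embedding = emb, state = state, history = history,
                 centroids = state$centroids,
                 Q = if (use_dec) soft_assign(emb$Z, state$centroids),
                 config = config),
            class = "finetune_result")
}
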