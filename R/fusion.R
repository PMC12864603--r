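# Fusion head and end-to-end training of the multi-view classifier.
#
# The selected fusion strategy is hierarchical: each 128-dimensional view
# passes through its own linear+ReLU stage, the two 64-dimensional summaries
# are concatenated, and two dropout-regularized fully connected layers plus a
# final logistic unit (three FC layers in total) produce the antioxidant
# probability. Concatenation (no per-view stage) and cross-attention (a
# learned linear cross-projection of each view added to the other; with
# single-vector "token sets" the softmax of scaled dot-product attention is
# identically 1, so the query/key maps drop out) are available as
# alternatives. Training minimizes mean binary cross-entropy with Adam and
# decoupled weight decay.

#' Fusion-head configuration
#'
#' @param strategy One of `"hierarchical"`, `"concatenation"`,
#'   `"cross_attention"`.
#' @param dropout Dropout rate applied after each hidden FC layer.
#' @param stage1_dim Width of the per-view stage in the hierarchical strategy.
#' @param fc_dims Widths of the two hidden FC layers.
#' @return A list of class `aop_fusion_config`.
#' @export
fusion_config <- function(strategy = c("hierarchical", "concatenation",
                                       "cross_attention"),
                          dropout = 0.2, stage1_dim = 64L,
                          fc_dims = c(64L, 32L)) {
  strategy <- match.arg(strategy)
  structure(
    list(strategy = strategy, dropout = dropout,
         stage1_dim = as.integer(stage1_dim), fc_dims = as.integer(fc_dims),
         fc_layers = 3L),
    class = "aop_fusion_config"
  )
}

#' Training configuration
#'
#' Defaults are the published optimum for the real benchmarks (learning rate
#' 1e-5, dropout 0.2, weight decay 3e-3, batch size 64). Small synthetic runs
#' typically use a larger learning rate and far fewer epochs; see the
#' vignette.
#'
#' @param learning_rate,weight_decay,dropout,batch_size Optimizer settings.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); ignored when no validation set is given.
#' @param seed Integer seed governing batch order, dropout masks and
#'   initialization-dependent streams.
#' @return A list of class `aop_train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, weight_decay = 3e-3,
                         dropout = 0.2, batch_size = 64L, max_epochs = 300L,
                         patience = 30L, seed = 1L) {
  structure(
    list(learning_rate = learning_rate, weight_decay = weight_decay,
         dropout = dropout, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "aop_train_config"
  )
}

init_head <- function(fus, view, seed, seq_dim = 128L, graph_dim = 128L) {
  if (seq_dim != graph_dim && view == "both") {
    stop_aopred("Both view embeddings must share one dimension for fusion.",
                "aopred_config_error")
  }
  with_seed(derive_seed(seed, "fusion-head-init"), {
    d <- if (view == "graph") graph_dim else seq_dim
    s1 <- fus$stage1_dim
    f1 <- fus$fc_dims[1]
    f2 <- fus$fc_dims[2]
    if (view != "both") {
      return(list(
        A1 = init_mat(d, s1), a1 = numeric(s1),
        W1 = init_mat(s1, f1, fan_in = s1), b1 = numeric(f1),
        W2 = init_mat(f1, f2, fan_in = f1), b2 = numeric(f2),
        w_out = init_mat(f2, 1L, fan_in = f2), b_out = numeric(1)
      ))
    }
    switch(fus$strategy,
      hierarchical = list(
        A1 = init_mat(d, s1), a1 = numeric(s1),
        A2 = init_mat(d, s1), a2 = numeric(s1),
        W1 = init_mat(2L * s1, f1, fan_in = 2L * s1), b1 = numeric(f1),
        W2 = init_mat(f1, f2, fan_in = f1), b2 = numeric(f2),
        w_out = init_mat(f2, 1L, fan_in = f2), b_out = numeric(1)
      ),
      concatenation = list(
        W1 = init_mat(2L * d, f1, fan_in = 2L * d), b1 = numeric(f1),
        W2 = init_mat(f1, f2, fan_in = f1), b2 = numeric(f2),
        w_out = init_mat(f2, 1L, fan_in = f2), b_out = numeric(1)
      ),
      cross_attention = list(
        Vsg = init_mat(d, d), Vgs = init_mat(d, d),
        W1 = init_mat(2L * d, f1, fan_in = 2L * d), b1 = numeric(f1),
        W2 = init_mat(f1, f2, fan_in = f1), b2 = numeric(f2),
        w_out = init_mat(f2, 1L, fan_in = f2), b_out = numeric(1)
      )
    )
  })
}

head_forward <- function(head, fus, view, S, G, training = FALSE) {
  n <- if (!is.null(S)) nrow(S) else nrow(G)
  cache <- list(S = S, G = G)
  if (view == "sequence") {
    Z1p <- S %*% head$A1 + rep(head$a1, each = n)
    Z <- pmax(Z1p, 0)
    cache$Z1p <- Z1p
  } else if (view == "graph") {
    Z1p <- G %*% head$A1 + rep(head$a1, each = n)
    Z <- pmax(Z1p, 0)
    cache$Z1p <- Z1p
  } else if (fus$strategy == "hierarchical") {
    S1p <- S %*% head$A1 + rep(head$a1, each = n)
    G1p <- G %*% head$A2 + rep(head$a2, each = n)
    Z <- cbind(pmax(S1p, 0), pmax(G1p, 0))
    cache$S1p <- S1p
    cache$G1p <- G1p
  } else if (fus$strategy == "concatenation") {
    Z <- cbind(S, G)
  } else { # cross_attention: each view augmented by a projection of the other
    Sx <- S + G %*% head$Vsg
    Gx <- G + S %*% head$Vgs
    Z <- cbind(Sx, Gx)
  }
  H1p <- Z %*% head$W1 + rep(head$b1, each = n)
  H1 <- pmax(H1p, 0)
  d1 <- dropout_forward(H1, fus$dropout, training)
  H2p <- d1$out %*% head$W2 + rep(head$b2, each = n)
  H2 <- pmax(H2p, 0)
  d2 <- dropout_forward(H2, fus$dropout, training)
  logits <- drop(d2$out %*% head$w_out) + head$b_out
  cache <- c(cache, list(Z = Z, H1p = H1p, H1d = d1$out, mask1 = d1$mask,
                         H2p = H2p, H2d = d2$out, mask2 = d2$mask, n = n))
  list(logits = logits, cache = cache)
}

head_backward <- function(head, fus, view, cache, dlogits) {
  n <- cache$n
  g <- list()
  dH2d <- matrix(dlogits, n, 1) %*% t(head$w_out)
  g$w_out <- crossprod(cache$H2d, matrix(dlogits, n, 1))
  g$b_out <- sum(dlogits)
  if (!is.null(cache$mask2)) dH2d <- dH2d * cache$mask2
  dH2p <- dH2d * (cache$H2p > 0)
  g$W2 <- crossprod(cache$H1d, dH2p)
  g$b2 <- colSums(dH2p)
  dH1d <- dH2p %*% t(head$W2)
  if (!is.null(cache$mask1)) dH1d <- dH1d * cache$mask1
  dH1p <- dH1d * (cache$H1p > 0)
  g$W1 <- crossprod(cache$Z, dH1p)
  g$b1 <- colSums(dH1p)
  dZ <- dH1p %*% t(head$W1)
  dS <- NULL
  dG <- NULL
  if (view == "sequence") {
    dZ1p <- dZ * (cache$Z1p > 0)
    g$A1 <- crossprod(cache$S, dZ1p)
    g$a1 <- colSums(dZ1p)
    dS <- dZ1p %*% t(head$A1)
  } else if (view == "graph") {
    dZ1p <- dZ * (cache$Z1p > 0)
    g$A1 <- crossprod(cache$G, dZ1p)
    g$a1 <- colSums(dZ1p)
    dG <- dZ1p %*% t(head$A1)
  } else if (fus$strategy == "hierarchical") {
    s1 <- ncol(head$A1)
    dS1 <- dZ[, seq_len(s1), drop = FALSE] * (cache$S1p > 0)
    dG1 <- dZ[, s1 + seq_len(s1), drop = FALSE] * (cache$G1p > 0)
    g$A1 <- crossprod(cache$S, dS1)
    g$a1 <- colSums(dS1)
    g$A2 <- crossprod(cache$G, dG1)
    g$a2 <- colSums(dG1)
    dS <- dS1 %*% t(head$A1)
    dG <- dG1 %*% t(head$A2)
  } else if (fus$strategy == "concatenation") {
    d <- ncol(cache$S)
    dS <- dZ[, seq_len(d), drop = FALSE]
    dG <- dZ[, d + seq_len(d), drop = FALSE]
  } else {
    d <- ncol(cache$S)
    dSx <- dZ[, seq_len(d), drop = FALSE]
    dGx <- dZ[, d + seq_len(d), drop = FALSE]
    g$Vsg <- crossprod(cache$G, dSx)
    g$Vgs <- crossprod(cache$S, dGx)
    dS <- dSx + dGx %*% t(head$Vgs)
    dG <- dGx + dSx %*% t(head$Vsg)
  }
  # reorder gradient list to match parameter list order
  g <- g[names(head)]
  list(grads = g, dS = dS, dG = dG)
}

#' Fuse one pair of view embeddings into a probability
#'
#' Evaluation-mode (dropout disabled) forward pass of the fusion head.
#'
#' @param head Head parameters (see [aop_model()]; `model$params$head`).
#' @param seq_emb,graph_emb Numeric vectors of length 128.
#' @param config A [fusion_config()] matching the head.
#' @return A probability in (0, 1).
#' @export
fuse <- function(head, seq_emb, graph_emb, config = fusion_config()) {
  if (length(seq_emb) != length(graph_emb)) {
    stop_aopred("fuse() expects two embeddings of one shared dimension.",
                "aopred_shape_error")
  }
  out <- head_forward(head, config, "both",
                      matrix(seq_emb, 1), matrix(graph_emb, 1),
                      training = FALSE)
  sigmoid(out$logits)
}

#' Construct an untrained multi-view classifier
#'
#' @param view `"both"` (the full two-view model) or `"sequence"`/`"graph"`
#'   for the single-view ablation variants built from the same components.
#' @param seq_config,graph_config,fusion Component configurations.
#' @param seed Integer seed for all initial draws.
#' @return An object of class `aop_model`.
#' @export
aop_model <- function(view = c("both", "sequence", "graph"),
                      seq_config = seq_encoder_config(),
                      graph_config = graph_encoder_config(),
                      fusion = fusion_config(), seed = 1) {
  view <- match.arg(view)
  params <- list()
  if (view != "graph") params$seq <- init_sequence_encoder(seq_config, seed)
  if (view != "sequence") params$graph <- init_graph_encoder(graph_config, seed)
  params$head <- init_head(fusion, view, seed,
                           seq_dim = seq_config$model_dim,
                           graph_dim = graph_config$readout_dim)
  structure(
    list(view = view, seq_config = seq_config, graph_config = graph_config,
         fusion = fusion, params = params, seed = seed),
    class = "aop_model"
  )
}

#' Total trainable parameter count of a model
#'
#' The sum of the sequence-encoder, graph-encoder and fusion-head counts.
#'
#' @param model An [aop_model()] or fitted `aop_fit`.
#' @return Total number of trainable scalars.
#' @export
count_total_params <- function(model) {
  if (inherits(model, "aop_fit")) model <- model$model
  param_count(model$params)
}

#' @export
print.aop_model <- function(x, ...) {
  cat("<aop_model> view =", x$view, "| strategy =", x$fusion$strategy,
      "|", format(count_total_params(x), big.mark = ","), "parameters\n")
  invisible(x)
}

model_forward <- function(model, tokens, gbatch, training = FALSE,
                          want_cache = FALSE) {
  S <- NULL; G <- NULL; seq_out <- NULL; graph_out <- NULL
  if (model$view != "graph") {
    seq_out <- seq_forward(model$params$seq, model$seq_config, tokens,
                           want_cache = want_cache)
    S <- seq_out$embedding
  }
  if (model$view != "sequence") {
    graph_out <- graph_batch_forward(model$params$graph, gbatch,
                                     model$graph_config,
                                     want_cache = want_cache)
    G <- graph_out$embedding
  }
  hf <- head_forward(model$params$head, model$fusion, model$view, S, G,
                     training = training)
  list(logits = hf$logits,
       cache = if (want_cache) {
         list(seq = seq_out$cache, graph = graph_out$cache, head = hf$cache)
       })
}

model_backward <- function(model, tokens, gbatch, cache, dlogits) {
  hb <- head_backward(model$params$head, model$fusion, model$view,
                      cache$head, dlogits)
  grads <- list()
  if (model$view != "graph") {
    grads$seq <- seq_backward(model$params$seq, model$seq_config, cache$seq,
                              hb$dS)
  }
  if (model$view != "sequence") {
    grads$graph <- graph_batch_backward(model$params$graph, gbatch,
                                        model$graph_config, cache$graph,
                                        hb$dG)
  }
  grads$head <- hb$grads
  grads
}

featurize_manifest <- function(model, manifest, cache = NULL) {
  out <- list(manifest = manifest)
  if (model$view != "sequence") {
    gc <- graph_cache(manifest, cache = cache)
    if (nrow(gc$skipped)) {
      warn(paste0("Skipping ", nrow(gc$skipped),
                  " record(s) whose graph conversion failed: ",
                  paste(head(gc$skipped$id, 5), collapse = ", ")))
      out$manifest <- manifest[!manifest$id %in% gc$skipped$id, ]
    }
    out$graphs <- gc$graphs[out$manifest$id]
    out$skipped <- gc$skipped
    out$cache <- gc$cache
  } else {
    out$skipped <- tibble::tibble(id = character(0), message = character(0))
  }
  out$tokens <- tokenize(out$manifest$sequence, model$seq_config$max_len)
  out
}

subset_tokens <- function(tokens, idx) {
  structure(
    list(values = tokens$values[idx, , drop = FALSE],
         true_length = tokens$true_length[idx]),
    class = "aop_tokens"
  )
}

eval_logits <- function(model, feat, chunk = 256L) {
  n <- nrow(feat$manifest)
  logits <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    gb <- if (model$view != "sequence") build_graph_batch(feat$graphs[idx])
    fw <- model_forward(model, subset_tokens(feat$tokens, idx), gb,
                        training = FALSE)
    logits[idx] <- fw$logits
  }
  logits
}

#' Train the multi-view classifier
#'
#' Minimizes mean binary cross-entropy over minibatches with Adam and
#' decoupled weight decay. When a validation set is given, the epoch with the
#' lowest validation loss is returned and training stops after `patience`
#' epochs without improvement. The whole path -- batch order, dropout masks,
#' initialization -- is deterministic given the seed.
#'
#' @param model An [aop_model()].
#' @param train A labeled manifest tibble.
#' @param valid Optional labeled manifest for early stopping.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `aop_fit` with elements `model` (trained),
#'   `history` (tibble), `best_epoch`, `config`, `skipped`.
#' @export
train_aop <- function(model, train, valid = NULL, config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "aop_model"))
  if (anyNA(train$label)) {
    stop_aopred("Training requires a fully labeled manifest.",
                "aopred_config_error")
  }
  model$fusion$dropout <- config$dropout
  feat <- featurize_manifest(model, train)
  y <- feat$manifest$label
  vfeat <- if (!is.null(valid)) featurize_manifest(model, valid, cache = feat$cache)
  params <- model$params
  opt <- adam_init(params)
  n <- nrow(feat$manifest)
  history <- vector("list", config$max_epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(n, start + config$batch_size - 1L)]
        gb <- if (model$view != "sequence") build_graph_batch(feat$graphs[idx])
        tk <- subset_tokens(feat$tokens, idx)
        model$params <- params
        fw <- model_forward(model, tk, gb, training = TRUE, want_cache = TRUE)
        l <- bce_with_logits(fw$logits, y[idx])
        if (!is.finite(l$loss)) {
          stop_aopred(
            sprintf("Non-finite loss at epoch %d (batch starting %d).",
                    epoch, start),
            "aopred_numeric_error"
          )
        }
        grads <- model_backward(model, tk, gb, fw$cache, l$grad)
        upd <- adam_step(params, grads, opt, lr = config$learning_rate,
                         weight_decay = config$weight_decay)
        params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + l$loss
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      vloss <- NA_real_
      vacc <- NA_real_
      if (!is.null(valid)) {
        model$params <- params
        vl <- eval_logits(model, vfeat)
        vloss <- bce_with_logits(vl, vfeat$manifest$label)$loss
        vacc <- mean(as.integer(vl >= 0) == vfeat$manifest$label)
        if (vloss < best$loss) {
          best <- list(loss = vloss, params = params, epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss, valid_loss = vloss,
        valid_accuracy = vacc
      )
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  valid %.4f  acc %.3f",
                        epoch, ep_loss, vloss, vacc))
      }
      if (!is.null(valid) && stall >= config$patience) break
    }
  })
  model$params <- if (!is.null(valid) && best$epoch > 0) best$params else params
  structure(
    list(
      model = model,
      history = dplyr::bind_rows(history),
      best_epoch = if (!is.null(valid)) best$epoch else
        max(dplyr::bind_rows(history)$epoch),
      config = config,
      skipped = feat$skipped
    ),
    class = "aop_fit"
  )
}

#' @export
print.aop_fit <- function(x, ...) {
  cat("<aop_fit> view =", x$model$view, "| epochs =", nrow(x$history),
      "| best =", x$best_epoch, "\n")
  invisible(x)
}

#' Predict antioxidant probabilities for a manifest
#'
#' @param object An `aop_fit`.
#' @param newdata A validated manifest tibble.
#' @param ... Unused.
#' @return A tibble with `id`, `probability` and `label` (1 when the
#'   probability is at least 0.5, so ties go to the positive class). Records
#'   whose graph conversion fails are reported in the `skipped` attribute and
#'   omitted.
#' @export
predict.aop_fit <- function(object, newdata, ...) {
  feat <- featurize_manifest(object$model, newdata)
  logits <- eval_logits(object$model, feat)
  p <- sigmoid(logits)
  out <- tibble::tibble(
    id = feat$manifest$id,
    probability = p,
    label = as.integer(p >= 0.5)
  )
  attr(out, "skipped") <- feat$skipped
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores every weight bit-exactly along with the component
#' configurations, the tokenizer table, the graph-featurizer version and the
#' training seed. Loading refuses a checkpoint whose featurizer version does
#' not match the installed one.
#'
#' @param fit An `aop_fit` (or bare `aop_model`).
#' @param path File path.
#' @return `path` (save) / the restored object (load).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(
    featurizer_version = FEATURIZER_VERSION,
    tokenizer = tokenizer_table(),
    package = as.character(utils::packageVersion("aopred")),
    fit = fit
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$featurizer_version, FEATURIZER_VERSION)) {
    stop_aopred(
      sprintf("Checkpoint featurizer version '%s' does not match installed '%s'.",
              ck$featurizer_version, FEATURIZER_VERSION),
      "aopred_version_error"
    )
  }
  ck$fit
}

#' @export
tidy.aop_fit <- function(x, ...) x$history

#' @export
glance.aop_fit <- function(x, ...) {
  tibble::tibble(
    view = x$model$view,
    strategy = x$model$fusion$strategy,
    parameters = count_total_params(x$model),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    best_valid_loss = if (all(is.na(x$history$valid_loss))) NA_real_ else
      min(x$history$valid_loss, na.rm = TRUE)
  )
}
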