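# Graph view: degree-conditioned message passing network (MPNN).
#
# Three message-passing steps. The message to vertex v is the sum over its
# neighbors u of the concatenation (h_u, e_vu) of neighbor state and edge
# feature; the update is h_v <- sigmoid(H[t, deg(v)] %*% m_v) with one learned
# matrix per step and vertex degree (degree clamped at 4, the maximum
# heavy-atom degree in standard residues). The readout is the vertex mean of
# final states followed by a linear projection to 128 dimensions -- both
# permutation invariant.

#' Graph encoder configuration
#'
#' `hidden_dim = 71` pins the reference parameter count at 75 k.
#'
#' @param hidden_dim Node-state width.
#' @param n_steps Number of message-passing steps.
#' @param max_degree Degree clamp for the update matrices.
#' @param readout_dim Output embedding dimension.
#' @return A list of class `aop_graph_config`.
#' @export
graph_encoder_config <- function(hidden_dim = 71L, n_steps = 3L,
                                 max_degree = 4L, readout_dim = 128L) {
  structure(
    list(
      hidden_dim = as.integer(hidden_dim), n_steps = as.integer(n_steps),
      max_degree = as.integer(max_degree), readout_dim = as.integer(readout_dim),
      node_dim = NODE_FEATURE_DIM, edge_dim = EDGE_FEATURE_DIM
    ),
    class = "aop_graph_config"
  )
}

#' Initialize graph-encoder parameters
#'
#' @param config A [graph_encoder_config()].
#' @param seed Integer seed.
#' @return Parameter list: input encoder `Win`/`bin`, update matrices
#'   `H[[t]][[degree]]` (message width -> hidden, no bias, matching the
#'   update equation literally), readout `Wr`/`br`.
#' @export
init_graph_encoder <- function(config = graph_encoder_config(), seed = 1) {
  hd <- config$hidden_dim
  w <- hd + config$edge_dim
  with_seed(derive_seed(seed, "graph-encoder-init"), {
    list(
      Win = init_mat(config$node_dim, hd, fan_in = config$node_dim),
      bin = numeric(hd),
      H = lapply(seq_len(config$n_steps), function(t) {
        lapply(seq_len(config$max_degree), function(dg) init_mat(w, hd, fan_in = w))
      }),
      Wr = init_mat(hd, config$readout_dim, fan_in = hd),
      br = numeric(config$readout_dim)
    )
  })
}

#' Count graph-encoder parameters
#'
#' @param params Parameters from [init_graph_encoder()].
#' @return Total number of trainable scalars.
#' @export
count_graph_params <- function(params) param_count(params)

# Directed incidence structure shared by the exposed step functions and the
# batched trainer.
graph_structure <- function(graph) {
  e <- graph$edges
  src <- c(e[, 1], e[, 2])
  dst <- c(e[, 2], e[, 1])
  eid <- rep(seq_len(graph$n_bonds), 2)
  degree <- tabulate(dst, nbins = graph$n_atoms)
  if (any(degree == 0) && graph$n_atoms > 1) {
    stop_aopred("Isolated vertex in molecular graph (impossible for a valid peptide).",
                "aopred_graph_error")
  }
  list(src = src, dst = dst, eid = eid, degree = degree)
}

#' One message-passing step: compute messages
#'
#' The message function concatenates the neighbor state with the edge
#' feature; messages sum over the neighborhood.
#'
#' @param graph A `mol_graph`.
#' @param states Matrix of node states (`n_atoms x hidden`).
#' @return Matrix of messages (`n_atoms x (hidden + edge_dim)`).
#' @export
message_step <- function(graph, states) {
  st <- graph_structure(graph)
  msg <- cbind(states[st$src, , drop = FALSE],
               graph$edge_features[st$eid, , drop = FALSE])
  m <- rowsum(msg, group = st$dst, reorder = TRUE)
  stopifnot(nrow(m) == graph$n_atoms)
  m
}

#' One message-passing step: degree-conditioned update
#'
#' `h_v <- sigmoid(H[t, min(deg(v), max_degree)] %*% m_v)`.
#'
#' @param params Parameters from [init_graph_encoder()].
#' @param graph A `mol_graph`.
#' @param messages Output of [message_step()].
#' @param t Step index (1-based).
#' @param config The matching [graph_encoder_config()].
#' @return Updated node-state matrix.
#' @export
update_step <- function(params, graph, messages, t,
                        config = graph_encoder_config()) {
  st <- graph_structure(graph)
  dg <- pmin(st$degree, config$max_degree)
  out <- matrix(0, graph$n_atoms, config$hidden_dim)
  for (d in unique(dg)) {
    idx <- which(dg == d)
    out[idx, ] <- sigmoid(messages[idx, , drop = FALSE] %*% params$H[[t]][[d]])
  }
  out
}

#' Permutation-invariant readout
#'
#' Mean of final node states projected linearly to the readout dimension.
#'
#' @param params Parameters from [init_graph_encoder()].
#' @param states Final node states.
#' @param graph A `mol_graph`.
#' @return A numeric vector of length `readout_dim`.
#' @export
readout <- function(params, states, graph) {
  if (graph$n_atoms == 0) {
    stop_aopred("Cannot read out an empty graph.", "aopred_graph_error")
  }
  drop(colMeans(states) %*% params$Wr) + params$br
}

#' Encode a molecular graph into a 128-dimensional embedding
#'
#' @param params Parameters from [init_graph_encoder()].
#' @param graph A `mol_graph`.
#' @param config The matching [graph_encoder_config()].
#' @return A numeric vector of length `readout_dim`.
#' @export
encode_graph <- function(params, graph, config = graph_encoder_config()) {
  h <- graph$node_features %*% params$Win + rep(params$bin, each = graph$n_atoms)
  for (t in seq_len(config$n_steps)) {
    h <- update_step(params, graph, message_step(graph, h), t, config)
  }
  readout(params, h, graph)
}

## ---------------------------------------------------------------------------
## Batched forward/backward used in training

build_graph_batch <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offset <- cumsum(c(0L, head(n_nodes, -1L)))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  EF <- do.call(rbind, lapply(graphs, function(g) g$edge_features))
  e_off <- cumsum(c(0L, vapply(head(graphs, -1L), function(g) g$n_bonds, integer(1))))
  src <- integer(0); dst <- integer(0); eid <- integer(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (g$n_bonds == 0) next
    src <- c(src, g$edges[, 1] + offset[i], g$edges[, 2] + offset[i])
    dst <- c(dst, g$edges[, 2] + offset[i], g$edges[, 1] + offset[i])
    eid <- c(eid, rep(seq_len(g$n_bonds) + e_off[i], 2))
  }
  total <- sum(n_nodes)
  degree <- tabulate(dst, nbins = total)
  if (any(degree == 0) && total > length(graphs)) {
    stop_aopred("Isolated vertex in a batched molecular graph.",
                "aopred_graph_error")
  }
  list(
    X = X, EF = EF, src = src, dst = dst, eid = eid,
    graph_id = rep(seq_along(graphs), n_nodes),
    n_nodes = n_nodes, n_graphs = length(graphs), degree = degree
  )
}

graph_batch_forward <- function(params, batch, config, want_cache = FALSE) {
  dg <- pmin(batch$degree, config$max_degree)
  deg_idx <- lapply(seq_len(config$max_degree), function(d) which(dg == d))
  h <- batch$X %*% params$Win + rep(params$bin, each = nrow(batch$X))
  steps <- vector("list", config$n_steps)
  h0 <- h
  for (t in seq_len(config$n_steps)) {
    msg <- cbind(h[batch$src, , drop = FALSE],
                 batch$EF[batch$eid, , drop = FALSE])
    M <- rowsum(msg, group = batch$dst, reorder = TRUE)
    hn <- matrix(0, nrow(h), config$hidden_dim)
    for (d in seq_len(config$max_degree)) {
      idx <- deg_idx[[d]]
      if (length(idx)) {
        hn[idx, ] <- sigmoid(M[idx, , drop = FALSE] %*% params$H[[t]][[d]])
      }
    }
    if (want_cache) steps[[t]] <- list(M = M, hn = hn)
    h <- hn
  }
  gm <- rowsum(h, group = batch$graph_id, reorder = TRUE) / batch$n_nodes
  emb <- gm %*% params$Wr + rep(params$br, each = batch$n_graphs)
  out <- list(embedding = emb)
  if (want_cache) {
    out$cache <- list(h0 = h0, steps = steps, gm = gm, deg_idx = deg_idx)
  }
  out
}

graph_batch_backward <- function(params, batch, config, cache, dEmb) {
  grads <- list(
    Win = matrix(0, config$node_dim, config$hidden_dim),
    bin = numeric(config$hidden_dim),
    H = lapply(seq_len(config$n_steps), function(t) {
      lapply(seq_len(config$max_degree), function(d) {
        matrix(0, config$hidden_dim + config$edge_dim, config$hidden_dim)
      })
    }),
    Wr = crossprod(cache$gm, dEmb),
    br = colSums(dEmb)
  )
  dgm <- dEmb %*% t(params$Wr)
  dh <- dgm[batch$graph_id, , drop = FALSE] / batch$n_nodes[batch$graph_id]
  w <- config$hidden_dim + config$edge_dim
  for (t in rev(seq_len(config$n_steps))) {
    s <- cache$steps[[t]]
    dpre <- dh * s$hn * (1 - s$hn)
    dM <- matrix(0, nrow(dh), w)
    for (d in seq_len(config$max_degree)) {
      idx <- cache$deg_idx[[d]]
      if (length(idx)) {
        dM[idx, ] <- dpre[idx, , drop = FALSE] %*% t(params$H[[t]][[d]])
        grads$H[[t]][[d]] <- crossprod(s$M[idx, , drop = FALSE],
                                       dpre[idx, , drop = FALSE])
      }
    }
    dmsg_h <- dM[batch$dst, seq_len(config$hidden_dim), drop = FALSE]
    dh <- matrix(0, nrow(dh), config$hidden_dim)
    agg <- rowsum(dmsg_h, group = batch$src, reorder = TRUE)
    dh[as.integer(rownames(agg)), ] <- agg
  }
  grads$Win <- crossprod(batch$X, dh)
  grads$bin <- colSums(dh)
  grads
}
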