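# Sequence view: tokenizer and the extended-LSTM encoder.
#
# The encoder embeds each residue token into a 128-dimensional space and runs
# a stack of three residual blocks -- (mLSTM, sLSTM, mLSTM), each followed by
# a residual position-wise feed-forward layer -- then mean-pools over the
# unpadded positions. The mLSTM keeps a matrix memory updated by an
# outer-product ("covariance") rule with scalar exponential gates per head;
# the sLSTM keeps a scalar memory per unit with exponential input/forget
# gating, a normalizer state, and the log-domain stabilizer
#   m_t = max(log f_t + m_{t-1}, log i_t),
# under which the effectively applied gates exp(log f_t + m_{t-1} - m_t) and
# exp(log i_t - m_t) stay finite for any bounded pre-activation.
#
# Training uses batched layer implementations; the per-step functions
# (lstm_cell_step, slstm_step, mlstm_step) expose exactly the same arithmetic
# for one sample and one step, and the tests pin the two routes together.

NORMALIZER_FLOOR <- 1e-6

#' Sequence encoder configuration
#'
#' The free dimensions (four heads, feed-forward expansion 4) are pinned so
#' that the reference encoder counts 0.70 M trainable parameters.
#'
#' @param model_dim Embedding and block width.
#' @param heads Number of mLSTM heads (`model_dim` must be divisible).
#' @param ffn_mult Feed-forward expansion factor.
#' @param block_pattern Ordered kinds of the three blocks.
#' @param max_len Fixed token-vector length (padding to this length).
#' @return A list of class `aop_seq_config`.
#' @export
seq_encoder_config <- function(model_dim = 128L, heads = 4L, ffn_mult = 4L,
                               block_pattern = c("mlstm", "slstm", "mlstm"),
                               max_len = MAX_PEPTIDE_LENGTH) {
  stopifnot(model_dim %% heads == 0, all(block_pattern %in% c("mlstm", "slstm")))
  structure(
    list(
      model_dim = as.integer(model_dim), heads = as.integer(heads),
      ffn_mult = as.integer(ffn_mult), block_pattern = block_pattern,
      vocab_size = 21L, pad_index = PAD_INDEX, max_len = as.integer(max_len)
    ),
    class = "aop_seq_config"
  )
}

#' Tokenize validated peptide sequences
#'
#' Maps residues to integer codes 0..19 (alphabetical over the one-letter
#' codes, A = 0 ... Y = 19) and right-pads with the padding index 20 to the
#' fixed length of 50. The mapping is a bijection per position, so distinct
#' sequences yield distinct token vectors.
#'
#' @param sequences Character vector of validated peptide sequences.
#' @param max_len Fixed output length.
#' @return An object of class `aop_tokens`: list with `values` (an
#'   `n x max_len` integer matrix) and `true_length`.
#' @export
#' @examples
#' tokenize("ACDE")$values[1, 1:6]
tokenize <- function(sequences, max_len = MAX_PEPTIDE_LENGTH) {
  if (length(sequences) == 0) {
    stop_aopred("No sequences to tokenize.", "aopred_validation_error")
  }
  sequences <- toupper(sequences)
  n <- length(sequences)
  lens <- nchar(sequences)
  if (any(lens > max_len)) {
    stop_aopred("Sequence longer than the fixed token length.",
                "aopred_validation_error")
  }
  values <- matrix(PAD_INDEX, n, max_len)
  codes <- setNames(seq_along(AA_ALPHABET) - 1L, AA_ALPHABET)
  for (i in seq_len(n)) {
    ch <- strsplit(sequences[i], "")[[1]]
    v <- codes[ch]
    if (anyNA(v)) {
      stop_aopred(
        paste0("Unknown residue in sequence ", i, ": ",
               paste(unique(ch[is.na(v)]), collapse = ", ")),
        "aopred_validation_error"
      )
    }
    if (length(v)) values[i, seq_along(v)] <- v
  }
  structure(list(values = values, true_length = lens), class = "aop_tokens")
}

#' Exported tokenizer table
#'
#' @return A tibble with columns `token` (the 20 residues plus `"<pad>"`) and
#'   `index` (the integer code used by [tokenize()]).
#' @export
tokenizer_table <- function() {
  tibble::tibble(
    token = c(AA_ALPHABET, "<pad>"),
    index = c(seq_along(AA_ALPHABET) - 1L, PAD_INDEX)
  )
}

## ---------------------------------------------------------------------------
## Single-step reference cells

#' One step of a classical LSTM cell
#'
#' Implements the textbook gate equations: sigmoid forget/input/output gates
#' and a tanh candidate acting on the concatenation `(h_prev, x_t)`:
#' `c_t = f ⊙ c_prev + i ⊙ c~`, `h_t = o ⊙ tanh(c_t)`. Provided as the
#' plain-LSTM baseline cell and as the reference point for the exponential
#' gating of [slstm_step()].
#'
#' @param params List with `W_f`, `W_i`, `W_c`, `W_o` (each `d x (d + d_in)`)
#'   and bias vectors `b_f`, `b_i`, `b_c`, `b_o`.
#' @param h_prev,c_prev State vectors of length `d`.
#' @param x_t Input vector of length `d_in`.
#' @return List with `h`, `c` and the gate intermediates `f`, `i`, `o`,
#'   `c_tilde`.
#' @export
lstm_cell_step <- function(params, h_prev, c_prev, x_t) {
  u <- c(h_prev, x_t)
  if (ncol(params$W_f) != length(u)) {
    stop_aopred("LSTM cell: shape mismatch between weights and (h, x).",
                "aopred_shape_error")
  }
  f <- sigmoid(drop(params$W_f %*% u) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% u) + params$b_i)
  c_tilde <- tanh(drop(params$W_c %*% u) + params$b_c)
  c_new <- f * c_prev + i * c_tilde
  o <- sigmoid(drop(params$W_o %*% u) + params$b_o)
  list(h = o * tanh(c_new), c = c_new, f = f, i = i, o = o, c_tilde = c_tilde)
}

#' One step of the sLSTM cell (exponential gating with stabilizer)
#'
#' Input and forget gates use exponential activations; the stabilizer state
#' `m_t = max(f_pre + m_prev, i_pre)` rescales both so the applied gates
#' `exp(f_pre + m_prev - m_t)` and `exp(i_pre - m_t)` never exceed 1. The
#' normalizer `n_t` tracks the accumulated gate mass and the hidden state is
#' `o ⊙ c_t / max(n_t, 1e-6)`. A common additive shift of both gate
#' pre-activations changes `m_t` by the same amount and leaves the step's
#' output unchanged.
#'
#' @param params List with per-gate input weights `W_i`, `W_f`, `W_z`, `W_o`
#'   (`d_in x d`), recurrent weights `R_i`, `R_f`, `R_z`, `R_o` (`d x d`) and
#'   biases `b_i`, `b_f`, `b_z`, `b_o`.
#' @param state List with `h`, `c`, `n`, `m` (use [slstm_state0()] to start).
#' @param x_t Input vector.
#' @return Updated state list, plus applied gates `f_applied`, `i_applied`
#'   and candidate `z`.
#' @export
slstm_step <- function(params, state, x_t) {
  pre <- function(W, R, b) drop(x_t %*% W) + drop(state$h %*% R) + b
  i_pre <- pre(params$W_i, params$R_i, params$b_i)
  f_pre <- pre(params$W_f, params$R_f, params$b_f)
  if (any(!is.finite(c(i_pre, f_pre)))) {
    stop_aopred("sLSTM: non-finite gate pre-activations.", "aopred_numeric_error")
  }
  z <- tanh(pre(params$W_z, params$R_z, params$b_z))
  o <- sigmoid(pre(params$W_o, params$R_o, params$b_o))
  m_new <- pmax(f_pre + state$m, i_pre)
  f_app <- exp(f_pre + state$m - m_new)
  i_app <- exp(i_pre - m_new)
  c_new <- f_app * state$c + i_app * z
  n_new <- f_app * state$n + i_app
  h_tilde <- c_new / pmax(n_new, NORMALIZER_FLOOR)
  list(
    h = o * h_tilde, c = c_new, n = n_new, m = m_new,
    f_applied = f_app, i_applied = i_app, z = z, o = o
  )
}

#' @rdname slstm_step
#' @param d State dimension.
#' @export
slstm_state0 <- function(d) {
  list(h = numeric(d), c = numeric(d), n = numeric(d), m = numeric(d))
}

#' One step of the mLSTM cell (matrix memory, covariance update)
#'
#' Keeps a `d_head x d_head` matrix memory updated by the covariance rule
#' `C_t = f_t C_{t-1} + i_t (v_t ⊗ k_t)` with scalar exponential gates
#' stabilized as in [slstm_step()]; the output reads the memory with a query:
#' `h = C_t q / max(|n_t . q|, 1e-6)`. The step has no dependence on absolute
#' position beyond the carried state.
#'
#' @param params List with `W_q`, `W_k`, `W_v` (`d_in x d_head`), gate weight
#'   vectors `w_i`, `w_f` (length `d_in`) and scalars `b_i`, `b_f`.
#' @param state List with `C` (matrix), `n` (vector), `m` (scalar); use
#'   [mlstm_state0()] to start.
#' @param x_t Input vector.
#' @return Updated state list plus `h` and applied gates.
#' @export
mlstm_step <- function(params, state, x_t) {
  if (any(!is.finite(x_t))) {
    stop_aopred("mLSTM: non-finite input.", "aopred_numeric_error")
  }
  d_head <- ncol(params$W_q)
  q <- drop(x_t %*% params$W_q)
  k <- drop(x_t %*% params$W_k) / sqrt(d_head)
  v <- drop(x_t %*% params$W_v)
  i_pre <- sum(params$w_i * x_t) + params$b_i
  f_pre <- sum(params$w_f * x_t) + params$b_f
  m_new <- max(f_pre + state$m, i_pre)
  f_app <- exp(f_pre + state$m - m_new)
  i_app <- exp(i_pre - m_new)
  C_new <- f_app * state$C + i_app * (v %o% k)
  n_new <- f_app * state$n + i_app * k
  den <- max(abs(sum(n_new * q)), NORMALIZER_FLOOR)
  list(
    C = C_new, n = n_new, m = m_new, h = drop(C_new %*% q) / den,
    f_applied = f_app, i_applied = i_app, q = q, k = k, v = v
  )
}

#' @rdname mlstm_step
#' @param d_head Head dimension.
#' @export
mlstm_state0 <- function(d_head) {
  list(C = matrix(0, d_head, d_head), n = numeric(d_head), m = 0)
}

## ---------------------------------------------------------------------------
## Parameter initialization

init_mlstm_layer <- function(d, heads) {
  list(
    Wq = init_mat(d, d), Wk = init_mat(d, d), Wv = init_mat(d, d),
    Wi = init_mat(d, heads), bi = numeric(heads),
    Wf = init_mat(d, heads), bf = numeric(heads),
    Wo = init_mat(d, d), bo = numeric(d),
    Wout = init_mat(d, d)
  )
}

init_slstm_layer <- function(d) {
  list(
    Wall = init_mat(d, 4 * d), Rall = init_mat(d, 4 * d), ball = numeric(4 * d)
  )
}

init_ffn <- function(d, mult) {
  list(
    W1 = init_mat(d, mult * d), b1 = numeric(mult * d),
    W2 = init_mat(mult * d, d, fan_in = mult * d), b2 = numeric(d)
  )
}

#' Initialize sequence-encoder parameters
#'
#' Recurrent and projection weights start small-uniform
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`), biases at zero; the draw is
#' deterministic given `seed`.
#'
#' @param config A [seq_encoder_config()].
#' @param seed Integer seed.
#' @return Nested parameter list (embedding + per-block parameters).
#' @export
init_sequence_encoder <- function(config = seq_encoder_config(), seed = 1) {
  d <- config$model_dim
  with_seed(derive_seed(seed, "seq-encoder-init"), {
    blocks <- lapply(config$block_pattern, function(kind) {
      rec <- if (kind == "mlstm") init_mlstm_layer(d, config$heads) else init_slstm_layer(d)
      list(kind = kind, rec = rec, ffn = init_ffn(d, config$ffn_mult))
    })
    list(embedding = init_mat(config$vocab_size, d, fan_in = d), blocks = blocks)
  })
}

#' Count sequence-encoder parameters
#'
#' @param params Parameters from [init_sequence_encoder()].
#' @return Total number of trainable scalars.
#' @export
count_sequence_params <- function(params) param_count(params)

## ---------------------------------------------------------------------------
## Batched layers (forward + hand-derived backward)
## Layout: activations are (B*T) x d matrices with row index b + B*(t-1).

mlstm_layer_forward <- function(p, X, B, T, heads) {
  d <- ncol(X)
  kd <- d %/% heads
  csc <- 1 / sqrt(kd)
  Q <- X %*% p$Wq
  K <- (X %*% p$Wk) * csc
  V <- X %*% p$Wv
  It <- X %*% p$Wi + rep(p$bi, each = nrow(X))
  Ft <- X %*% p$Wf + rep(p$bf, each = nrow(X))
  Opre <- X %*% p$Wo + rep(p$bo, each = nrow(X))
  O <- sigmoid(Opre)
  Htil <- matrix(0, nrow(X), d)
  att <- vector("list", B * heads)
  upper <- upper.tri(matrix(0, T, T))
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(T) - 1L)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * kd + 1L):(h * kd)
      q <- Q[rows, cols, drop = FALSE]
      k <- K[rows, cols, drop = FALSE]
      v <- V[rows, cols, drop = FALSE]
      Fc <- cumsum(Ft[rows, h])
      D <- outer(Fc, Fc, "-") + matrix(It[rows, h], T, T, byrow = TRUE)
      D[upper] <- -Inf
      m <- pmax(apply(D, 1, max), Fc) # Fc branch = initial state with m_0 = 0
      W <- exp(D - m) # column recycling subtracts m_t from row t
      P <- tcrossprod(q, k)
      G <- W * P
      num <- G %*% v
      dvec <- rowSums(G)
      den <- pmax(abs(dvec), NORMALIZER_FLOOR)
      Htil[rows, cols] <- num / den
      att[[(b - 1L) * heads + h]] <- list(W = W, P = P, dvec = dvec, den = den)
    }
  }
  Hg <- O * Htil
  Y <- X + Hg %*% p$Wout
  list(
    out = Y,
    cache = list(X = X, Q = Q, K = K, V = V, O = O, Htil = Htil, Hg = Hg,
                 att = att, B = B, T = T, heads = heads, kd = kd, csc = csc)
  )
}

mlstm_layer_backward <- function(p, cache, dY) {
  X <- cache$X
  B <- cache$B; T <- cache$T; heads <- cache$heads; kd <- cache$kd
  dX <- dY
  dHg <- dY %*% t(p$Wout)
  dWout <- crossprod(cache$Hg, dY)
  dO <- dHg * cache$Htil
  dHtil <- dHg * cache$O
  dOpre <- dO * cache$O * (1 - cache$O)
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- dQ; dV <- dQ
  dIt <- matrix(0, nrow(X), heads)
  dFt <- dIt
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(T) - 1L)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * kd + 1L):(h * kd)
      a <- cache$att[[(b - 1L) * heads + h]]
      q <- cache$Q[rows, cols, drop = FALSE]
      k <- cache$K[rows, cols, drop = FALSE]
      v <- cache$V[rows, cols, drop = FALSE]
      dHt <- dHtil[rows, cols, drop = FALSE]
      num <- cache$Htil[rows, cols, drop = FALSE] * a$den
      dnum <- dHt / a$den
      active <- abs(a$dvec) > NORMALIZER_FLOOR
      dd <- ifelse(active, -rowSums(dHt * num) / a$den^2 * sign(a$dvec), 0)
      dG <- tcrossprod(dnum, v) + dd # dd recycles down columns: adds dd[t] to row t
      dV[rows, cols] <- dV[rows, cols] + crossprod(a$W * a$P, dnum)
      dP <- dG * a$W
      dW <- dG * a$P
      dQ[rows, cols] <- dQ[rows, cols] + dP %*% k
      dK[rows, cols] <- dK[rows, cols] + crossprod(dP, q)
      dD <- dW * a$W # stabilizer m detached
      dIt[rows, h] <- dIt[rows, h] + colSums(dD)
      dFbar <- rowSums(dD) - colSums(dD)
      dFt[rows, h] <- dFt[rows, h] + rev(cumsum(rev(dFbar)))
    }
  }
  csc <- cache$csc
  grads <- list(
    Wq = crossprod(X, dQ), Wk = crossprod(X, dK) * csc, Wv = crossprod(X, dV),
    Wi = crossprod(X, dIt), bi = colSums(dIt),
    Wf = crossprod(X, dFt), bf = colSums(dFt),
    Wo = crossprod(X, dOpre), bo = colSums(dOpre),
    Wout = dWout
  )
  dX <- dX + dOpre %*% t(p$Wo) + dQ %*% t(p$Wq) + (dK %*% t(p$Wk)) * csc +
    dV %*% t(p$Wv) + dIt %*% t(p$Wi) + dFt %*% t(p$Wf)
  list(grads = grads, dX = dX)
}

slstm_layer_forward <- function(p, X, B, T) {
  d <- ncol(X) # gate order in Wall/Rall/ball: i, f, z, o
  preX <- X %*% p$Wall + rep(p$ball, each = nrow(X))
  h <- matrix(0, B, d); cc <- h; nn <- h; mm <- h
  H <- matrix(0, nrow(X), d)
  steps <- vector("list", T)
  ix_i <- seq_len(d); ix_f <- d + ix_i; ix_z <- 2 * d + ix_i; ix_o <- 3 * d + ix_i
  for (t in seq_len(T)) {
    rows <- B * (t - 1L) + seq_len(B)
    pre <- preX[rows, , drop = FALSE] + h %*% p$Rall
    i_pre <- pre[, ix_i, drop = FALSE]
    f_pre <- pre[, ix_f, drop = FALSE]
    z <- tanh(pre[, ix_z, drop = FALSE])
    o <- sigmoid(pre[, ix_o, drop = FALSE])
    m_new <- pmax(f_pre + mm, i_pre)
    fp <- exp(f_pre + mm - m_new)
    ip <- exp(i_pre - m_new)
    c_new <- fp * cc + ip * z
    n_new <- fp * nn + ip
    htil <- c_new / pmax(n_new, NORMALIZER_FLOOR)
    h_new <- o * htil
    steps[[t]] <- list(h_prev = h, c_prev = cc, n_prev = nn, fp = fp, ip = ip,
                       z = z, o = o, c = c_new, n = n_new, htil = htil)
    h <- h_new; cc <- c_new; nn <- n_new; mm <- m_new
    H[rows, ] <- h_new
  }
  list(out = X + H, cache = list(X = X, steps = steps, B = B, T = T))
}

slstm_layer_backward <- function(p, cache, dY) {
  X <- cache$X
  B <- cache$B; T <- cache$T
  d <- ncol(X)
  dpreX <- matrix(0, nrow(X), 4 * d)
  dRall <- matrix(0, d, 4 * d)
  dh_rec <- matrix(0, B, d)
  dc_car <- dh_rec; dn_car <- dh_rec
  ix_i <- seq_len(d); ix_f <- d + ix_i; ix_z <- 2 * d + ix_i; ix_o <- 3 * d + ix_i
  for (t in rev(seq_len(T))) {
    rows <- B * (t - 1L) + seq_len(B)
    s <- cache$steps[[t]]
    dh <- dY[rows, , drop = FALSE] + dh_rec
    do_ <- dh * s$htil
    dhtil <- dh * s$o
    den <- pmax(s$n, NORMALIZER_FLOOR)
    dc <- dhtil / den + dc_car
    dn <- ifelse(s$n > NORMALIZER_FLOOR, -dhtil * s$c / den^2, 0) + dn_car
    dfp <- dc * s$c_prev + dn * s$n_prev
    dip <- dc * s$z + dn
    dpre <- matrix(0, B, 4 * d)
    dpre[, ix_i] <- dip * s$ip # stabilizer m detached
    dpre[, ix_f] <- dfp * s$fp
    dpre[, ix_z] <- (dc * s$ip) * (1 - s$z^2)
    dpre[, ix_o] <- do_ * s$o * (1 - s$o)
    dpreX[rows, ] <- dpre
    dRall <- dRall + crossprod(s$h_prev, dpre)
    dh_rec <- dpre %*% t(p$Rall)
    dc_car <- dc * s$fp
    dn_car <- dn * s$fp
  }
  grads <- list(Wall = crossprod(X, dpreX), Rall = dRall, ball = colSums(dpreX))
  list(grads = grads, dX = dY + dpreX %*% t(p$Wall))
}

ffn_forward <- function(p, X) {
  A <- X %*% p$W1 + rep(p$b1, each = nrow(X))
  R <- pmax(A, 0)
  list(out = X + R %*% p$W2 + rep(p$b2, each = nrow(X)),
       cache = list(X = X, A = A, R = R))
}

ffn_backward <- function(p, cache, dY) {
  dR <- dY %*% t(p$W2)
  dA <- dR * (cache$A > 0)
  grads <- list(
    W1 = crossprod(cache$X, dA), b1 = colSums(dA),
    W2 = crossprod(cache$R, dY), b2 = colSums(dY)
  )
  list(grads = grads, dX = dY + dA %*% t(p$W1))
}

## ---------------------------------------------------------------------------
## Full encoder

seq_forward <- function(params, config, tokens, want_cache = FALSE) {
  values <- tokens$values
  lens <- tokens$true_length
  if (any(lens == 0)) {
    stop_aopred("Cannot encode a zero-length sequence.", "aopred_validation_error")
  }
  B <- nrow(values); T <- ncol(values)
  idx <- as.vector(values) + 1L # column-major: row index b + B*(t-1)
  X <- params$embedding[idx, , drop = FALSE]
  caches <- list()
  for (i in seq_along(params$blocks)) {
    blk <- params$blocks[[i]]
    rec <- if (blk$kind == "mlstm") {
      mlstm_layer_forward(blk$rec, X, B, T, config$heads)
    } else {
      slstm_layer_forward(blk$rec, X, B, T)
    }
    ffn <- ffn_forward(blk$ffn, rec$out)
    X <- ffn$out
    if (want_cache) caches[[i]] <- list(rec = rec$cache, ffn = ffn$cache)
  }
  # masked mean pooling over the true sequence positions
  tpos <- rep(seq_len(T), each = B)
  bidx <- rep(seq_len(B), T)
  w <- as.numeric(tpos <= lens[bidx]) / lens[bidx]
  emb <- rowsum(X * w, group = bidx, reorder = TRUE)
  out <- list(embedding = emb)
  if (want_cache) {
    out$cache <- list(caches = caches, idx = idx, w = w, bidx = bidx,
                      B = B, T = T)
  }
  out
}

seq_backward <- function(params, config, cache, dEmb) {
  dX <- dEmb[cache$bidx, , drop = FALSE] * cache$w
  gblocks <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    blk <- params$blocks[[i]]
    ff <- ffn_backward(blk$ffn, cache$caches[[i]]$ffn, dX)
    rec <- if (blk$kind == "mlstm") {
      mlstm_layer_backward(blk$rec, cache$caches[[i]]$rec, ff$dX)
    } else {
      slstm_layer_backward(blk$rec, cache$caches[[i]]$rec, ff$dX)
    }
    gblocks[[i]] <- list(kind = blk$kind, rec = rec$grads, ffn = ff$grads)
    dX <- rec$dX
  }
  dE <- matrix(0, nrow(params$embedding), ncol(params$embedding))
  agg <- rowsum(dX, group = cache$idx, reorder = FALSE)
  dE[as.integer(rownames(agg)), ] <- agg
  list(embedding = dE, blocks = gblocks)
}

#' Encode peptide sequences into 128-dimensional embeddings
#'
#' Runs the token embedding, the three residual xLSTM blocks and masked mean
#' pooling over the unpadded positions. Because pooling is masked and the
#' recurrences are causal, appending extra padding never changes the
#' embedding.
#'
#' @param params Parameters from [init_sequence_encoder()].
#' @param tokens An [tokenize()] result (or a character vector of validated
#'   sequences, tokenized on the fly).
#' @param config The matching [seq_encoder_config()].
#' @return An `n x model_dim` matrix of embeddings.
#' @export
encode_sequence <- function(params, tokens, config = seq_encoder_config()) {
  if (is.character(tokens)) tokens <- tokenize(tokens, config$max_len)
  seq_forward(params, config, tokens)$embedding
}
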