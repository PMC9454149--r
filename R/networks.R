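#' @name networks
#' @title Actor and critic convolutional networks
#'
#' @description
#' Both networks share the same 6-layer family: a parallel block of three
#' independent 3-D convolution paths (filter counts 4/8/8) whose "same"
#' border mode preserves the spatial extent, channel concatenation, a
#' 3x3x3 max pool (stride 3, no padding), flatten, a 256-unit ReLU dense
#' layer, and a head. The actor head is one 6-way softmax (single-atom
#' ligand) or two parallel 6-way softmaxes (translation + rotation,
#' multi-atom); the critic head is a single tanh unit, so its output lies
#' in (-1, 1) like the long-term reward it estimates. Filter edges are
#' (2,3,4) for the single-atom variant and (4,5,6) for sulfate; even edges
#' pad the extra cell on the high side of each axis.
NULL

#' Parallel-path filter edge lengths for a ligand variant
#'
#' @param variant \code{"single"} (copper-like) or \code{"multi"}
#'   (sulfate-like).
#' @return Integer vector of three filter edge lengths.
#' @export
filter_sizes <- function(variant = c("single", "multi")) {
  variant <- match.arg(variant)
  if (variant == "single") c(2L, 3L, 4L) else c(4L, 5L, 6L)
}

#' Network configuration
#'
#' @param grid_dim Spatial edge of the input grid (voxels).
#' @param n_channels Input channel count N.
#' @param variant \code{"single"} or \code{"multi"} (decides the default
#'   filter sizes and the actor head count).
#' @param filters Filter counts of the three parallel paths.
#' @param sizes Filter edge lengths; defaults to
#'   \code{\link{filter_sizes}(variant)}.
#' @param dense_units Width of the fully connected layer.
#' @param pool Max-pool edge (= stride).
#' @param input_scale Fixed multiplier applied to the input densities
#'   before the first convolution. A normalized atom splat puts only about
#'   0.05 of mass in its central voxel, which starves the activations;
#'   scaling by 20 brings a heavy atom's peak voxel to order 1 so the
#'   conventional weight initialization sees inputs on its design scale.
#' @return A \code{net_config}.
#' @export
net_config <- function(grid_dim = 18L, n_channels = 22L,
                       variant = c("single", "multi"),
                       filters = c(4L, 8L, 8L), sizes = NULL,
                       dense_units = 256L, pool = 3L, input_scale = 20) {
  variant <- match.arg(variant)
  if (is.null(sizes)) sizes <- filter_sizes(variant)
  stopifnot(length(filters) == length(sizes), grid_dim %% pool == 0,
            input_scale > 0)
  structure(list(grid_dim = as.integer(grid_dim),
                 n_channels = as.integer(n_channels),
                 variant = variant,
                 filters = as.integer(filters), sizes = as.integer(sizes),
                 dense_units = as.integer(dense_units),
                 pool = as.integer(pool), input_scale = input_scale),
            class = "net_config")
}

# Glorot-uniform initialization, explicit fan-in/out
.glorot <- function(dims, fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -s, s), dim = dims)
}

#' Build an actor or critic network
#'
#' @param type \code{"actor"} or \code{"critic"}.
#' @param config A \code{net_config}.
#' @param seed Integer seed for weight initialization (Glorot uniform);
#'   identical (config, seed) pairs give identical parameters.
#' @return A \code{network}: list with \code{type}, \code{config} and
#'   \code{params}.
#' @export
build_network <- function(type = c("actor", "critic"), config = net_config(),
                          seed = 1L) {
  type <- match.arg(type)
  cfg <- config
  flat <- (cfg$grid_dim %/% cfg$pool)^3 * sum(cfg$filters)
  with_seed_(seed, {
    conv <- lapply(seq_along(cfg$filters), function(p) {
      k <- cfg$sizes[p]; f <- cfg$filters[p]
      fan_in <- k^3 * cfg$n_channels
      list(w = .glorot(c(k, k, k, cfg$n_channels, f), fan_in, k^3 * f),
           b = numeric(f))
    })
    params <- list(conv = conv,
                   W1 = .glorot(c(cfg$dense_units, flat), flat, cfg$dense_units),
                   b1 = numeric(cfg$dense_units))
    # the head starts near zero (0.1 x Glorot): the initial policy is then
    # close to uniform and the initial value close to 0, standard practice
    # for policy-gradient heads
    if (type == "actor") {
      params$W2 <- 0.1 * .glorot(c(6L, cfg$dense_units), cfg$dense_units, 6L)
      params$b2 <- numeric(6L)
      if (cfg$variant == "multi") {
        params$W2r <- 0.1 * .glorot(c(6L, cfg$dense_units), cfg$dense_units, 6L)
        params$b2r <- numeric(6L)
      }
    } else {
      params$W2 <- 0.1 * .glorot(c(1L, cfg$dense_units), cfg$dense_units, 1L)
      params$b2 <- numeric(1L)
    }
    structure(list(type = type, config = cfg, params = params),
              class = "network")
  })
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Forward pass
#'
#' @param net A \code{network}.
#' @param x Input density array \code{(d, d, d, N)} matching the config.
#' @param keep Keep intermediate activations for \code{\link{net_backward}}.
#' @return For an actor: list with \code{probs} (6-vector) and, for the
#'   multi variant, \code{probs_rot}; for a critic: list with \code{value}
#'   in (-1, 1). With \code{keep = TRUE} a \code{cache} element is added.
#' @export
net_forward <- function(net, x, keep = FALSE) {
  cfg <- net$config
  dm <- dim(x)
  if (!identical(as.integer(dm),
                 c(rep(cfg$grid_dim, 3L), cfg$n_channels))) {
    stop("input shape mismatch: got ", paste(dm, collapse = "x"))
  }
  xdim <- as.integer(dm)
  x <- x * cfg$input_scale
  z <- vector("list", length(cfg$filters))
  a <- vector("list", length(cfg$filters))
  for (p in seq_along(cfg$filters)) {
    cp <- net$params$conv[[p]]
    z[[p]] <- conv3d_forward(x, cp$w, cp$b, xdim, cfg$sizes[p])
    a[[p]] <- pmax(z[[p]], 0)
  }
  concat <- array(unlist(a, use.names = FALSE),
                  dim = c(xdim[1:3], sum(cfg$filters)))
  mp <- maxpool3d_forward(concat, dim(concat), cfg$pool)
  v <- as.numeric(mp$y)
  h1 <- drop(net$params$W1 %*% v) + net$params$b1
  a1 <- pmax(h1, 0)
  z2 <- drop(net$params$W2 %*% a1) + net$params$b2
  out <- if (net$type == "actor") {
    res <- list(probs = softmax(z2))
    if (cfg$variant == "multi") {
      z2r <- drop(net$params$W2r %*% a1) + net$params$b2r
      res$probs_rot <- softmax(z2r)
      res$z2r <- z2r
    }
    res
  } else {
    list(value = tanh(z2))
  }
  if (keep) {
    out$cache <- list(x = x, z = z, concat_dim = dim(concat),
                      argmax = mp$argmax, pool_dim = dim(mp$y),
                      v = v, h1 = h1, a1 = a1, z2 = z2)
  }
  out
}

#' Backward pass
#'
#' Backpropagates a gradient given at the head's pre-activation (the
#' softmax logits for an actor, the pre-tanh unit for a critic) through the
#' network, returning parameter gradients in the same structure as
#' \code{net$params}. Loss-specific head gradients are the caller's job
#' (see \code{\link{compute_losses}}).
#'
#' @param net A \code{network}.
#' @param cache The \code{cache} from \code{net_forward(..., keep = TRUE)}.
#' @param dlogits Gradient w.r.t. head pre-activation: 6-vector (actor),
#'   scalar (critic).
#' @param dlogits_rot Gradient for the rotation head (multi-variant actor).
#' @return List of gradients mirroring \code{net$params}.
#' @export
net_backward <- function(net, cache, dlogits, dlogits_rot = NULL) {
  cfg <- net$config
  g <- list()
  g$W2 <- outer(as.numeric(dlogits), cache$a1)
  g$b2 <- as.numeric(dlogits)
  da1 <- drop(crossprod(net$params$W2, as.numeric(dlogits)))
  if (!is.null(dlogits_rot)) {
    g$W2r <- outer(as.numeric(dlogits_rot), cache$a1)
    g$b2r <- as.numeric(dlogits_rot)
    da1 <- da1 + drop(crossprod(net$params$W2r, as.numeric(dlogits_rot)))
  }
  dh1 <- da1 * (cache$h1 > 0)
  g$W1 <- outer(dh1, cache$v)
  g$b1 <- dh1
  dv <- drop(crossprod(net$params$W1, dh1))
  dpool <- array(dv, dim = cache$pool_dim)
  dconcat <- maxpool3d_backward(dpool, cache$argmax,
                                as.integer(cache$concat_dim))
  g$conv <- vector("list", length(cfg$filters))
  ch0 <- 0L
  xdim <- as.integer(dim(cache$x))
  for (p in seq_along(cfg$filters)) {
    f <- cfg$filters[p]
    dz <- dconcat[, , , ch0 + seq_len(f), drop = FALSE] * (cache$z[[p]] > 0)
    bw <- conv3d_backward(cache$x, net$params$conv[[p]]$w, dz, xdim,
                          cfg$sizes[p], f)
    g$conv[[p]] <- list(w = bw$dw, b = bw$db)
    ch0 <- ch0 + f
  }
  g
}

#' Number of parameters of a network
#' @param net A \code{network}.
#' @return Integer count.
#' @export
n_params <- function(net) {
  sum(vapply(rapply(net$params, length, how = "unlist"), identity, 1))
}

# ---- gradient bookkeeping -------------------------------------------------

zero_grads <- function(net) {
  rapply(net$params, function(p) array(0, dim = dim(p) %||% length(p)),
         how = "replace")
}

# lists combine by name when named (net_backward's field order differs
# from the params order), by position otherwise (the conv path list)
add_grads <- function(a, b) {
  if (is.list(a)) {
    if (!is.null(names(a))) b <- b[names(a)]
    return(mapply(add_grads, a, b, SIMPLIFY = FALSE))
  }
  a + b
}

scale_grads <- function(a, s) {
  if (is.list(a)) return(lapply(a, scale_grads, s = s))
  a * s
}

grad_norm <- function(g) {
  sqrt(sum(unlist(rapply(g, function(x) sum(x^2), how = "unlist"))))
}

#' Apply an RMSProp step
#'
#' Root-mean-square propagation, the optimizer conventionally paired with
#' asynchronous advantage actor-critic learners: per-parameter accumulators
#' \code{G <- rho G + (1 - rho) g^2} divide the gradient, so update sizes
#' adapt to the (often tiny) raw gradient scale of sparse density inputs.
#' The accumulator state lives in \code{net$opt} and is created on first
#' use. Global gradient-norm clipping is applied before the accumulator
#' update.
#'
#' @param net A \code{network}.
#' @param grads Gradient list from \code{\link{net_backward}} (accumulated).
#' @param lr Learning rate.
#' @param clip Global norm clip; Inf disables.
#' @param rho Accumulator decay.
#' @param eps Numerical floor inside the square root.
#' @return The updated network (parameters and optimizer state).
#' @export
rmsprop_update <- function(net, grads, lr, clip = 40, rho = 0.99,
                           eps = 1e-6) {
  nrm <- grad_norm(grads)
  if (is.finite(clip) && nrm > clip) grads <- scale_grads(grads, clip / nrm)
  if (is.null(net$opt)) {
    net$opt <- rapply(net$params, function(p) p * 0, how = "replace")
  }
  upd <- function(p, g, G) {
    if (is.list(p)) {
      if (!is.null(names(p))) { g <- g[names(p)]; G <- G[names(p)] }
      r <- mapply(upd, p, g, G, SIMPLIFY = FALSE)
      return(list(p = lapply(r, `[[`, "p"), G = lapply(r, `[[`, "G")))
    }
    G2 <- rho * G + (1 - rho) * g^2
    list(p = p - lr * g / sqrt(G2 + eps), G = G2)
  }
  r <- upd(net$params, grads, net$opt)
  net$params <- r$p
  net$opt <- r$G
  net
}

#' Apply a (clipped) SGD step
#'
#' Plain stochastic gradient descent with global gradient-norm clipping.
#'
#' @param net A \code{network}.
#' @param grads Gradient list from \code{\link{net_backward}} (accumulated).
#' @param lr Learning rate.
#' @param clip Global norm clip; Inf disables.
#' @return The updated network.
#' @export
sgd_update <- function(net, grads, lr, clip = 40) {
  nrm <- grad_norm(grads)
  if (is.finite(clip) && nrm > clip) grads <- scale_grads(grads, clip / nrm)
  step <- function(p, g) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]
      return(mapply(step, p, g, SIMPLIFY = FALSE))
    }
    p - lr * g
  }
  net$params <- step(net$params, grads)
  net
}

# ---- checkpoints ----------------------------------------------------------

config_hash <- function(config, channel_map = NULL) {
  payload <- jsonlite::toJSON(list(config = unclass(config),
                                   channels = unclass(channel_map)),
                              auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(payload), f)
  unname(tools::md5sum(f))
}

#' Save actor/critic checkpoint
#'
#' Stores parameters together with the full architecture config and a hash
#' of (config, channel map); \code{\link{load_checkpoint}} refuses to load
#' into a mismatching run.
#'
#' @param actor,critic \code{network} objects.
#' @param path Destination file (RDS).
#' @param channel_map The \code{channel_map} of the run.
#' @param extra Optional list stored verbatim (e.g. training progress).
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(actor, critic, path, channel_map = NULL,
                            extra = list()) {
  saveRDS(list(actor = actor, critic = critic,
               hash = config_hash(actor$config, channel_map),
               extra = extra), path)
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path Checkpoint file from \code{\link{save_checkpoint}}.
#' @param config Expected \code{net_config} (actor's).
#' @param channel_map Expected \code{channel_map}.
#' @return List with \code{actor}, \code{critic}, \code{extra}.
#' @export
load_checkpoint <- function(path, config = NULL, channel_map = NULL) {
  ck <- readRDS(path)
  if (!is.null(config)) {
    if (!identical(ck$hash, config_hash(config, channel_map))) {
      stop("checkpoint config hash mismatch; refusing to load")
    }
  }
  ck
}
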