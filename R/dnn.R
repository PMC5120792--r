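# Feed-forward articulatory-to-acoustic network: leaky-rectifier hidden
# layers trained by successive layer addition, each stage minimizing the
# frame MSE with Polak-Ribiere conjugate-gradient updates on shuffled
# blocks, with patience-based early stopping on a validation item split.

#' Gaussian layer initialization
#'
#' Weights are i.i.d. Gaussian with mean zero and standard deviation `1/N`,
#' `N` the number of units of the previous layer; biases start at zero.
#'
#' @param n_in,n_out layer dimensions.
#' @param seed optional integer seed.
#' @return List with `W` (n_in x n_out) and `b` (length n_out).
#' @export
init_layer <- function(n_in, n_out, seed = NULL) {
  if (n_in < 1 || n_out < 1) stop("layer dimensions must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  list(W = matrix(rnorm(n_in * n_out, sd = 1 / n_in), n_in, n_out),
       b = numeric(n_out))
}

#' Frame mean squared error
#'
#' `sum((o - m)^2) / D` for a pair of D-vectors; for matrices (frames in
#' rows) the per-frame MSEs are averaged, which equals the element-wise
#' mean of squared differences.
#'
#' @param predicted,target numeric vectors or equal-shaped matrices.
#' @return Scalar MSE.
#' @export
mse_loss <- function(predicted, target) {
  if (length(predicted) != length(target)) stop("length mismatch")
  mean((predicted - target)^2)
}

lrelu <- function(a, slope) {
  neg <- a < 0
  a[neg] <- slope * a[neg]
  a
}

lrelu_grad <- function(a, slope) {
  g <- array(1, dim(a))
  g[a < 0] <- slope
  g
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

new_dnn_model <- function(layers, slope, in_norm = NULL, out_norm = NULL) {
  structure(list(layers = layers, slope = slope,
                 in_norm = in_norm, out_norm = out_norm),
            class = "dnn_model")
}

#' @export
print.dnn_model <- function(x, ...) {
  sizes <- c(nrow(x$layers[[1]]$W),
             vapply(x$layers, function(l) ncol(l$W), 0L))
  cat(sprintf("<dnn_model: %s, leaky slope %g%s>\n",
              paste(sizes, collapse = "-"), x$slope,
              if (is.null(x$in_norm)) ", unnormalized" else ""))
  invisible(x)
}

# forward pass on z-scored input; returns z-scored output (and activations
# for backprop when keep = TRUE)
dnn_forward_z <- function(layers, slope, X, keep = FALSE) {
  L <- length(layers)
  acts <- if (keep) vector("list", L) else NULL
  H <- X
  for (l in seq_len(L)) {
    A <- add_bias(H %*% layers[[l]]$W, layers[[l]]$b)
    if (l < L) {
      if (keep) acts[[l]] <- A
      H <- lrelu(A, slope)
    } else H <- A
  }
  if (keep) list(out = H, acts = acts, input = X) else H
}

# loss + gradient of the elementwise-mean squared error for one block.
# Returns f and the gradient as a layers-shaped list.
dnn_loss_grad <- function(layers, slope, X, Y) {
  L <- length(layers)
  hs <- vector("list", L + 1)  # hs[[l]] = input to layer l
  as_ <- vector("list", L)
  hs[[1]] <- X
  for (l in seq_len(L)) {
    A <- add_bias(hs[[l]] %*% layers[[l]]$W, layers[[l]]$b)
    as_[[l]] <- A
    hs[[l + 1]] <- if (l < L) lrelu(A, slope) else A
  }
  O <- hs[[L + 1]]
  f <- mean((O - Y)^2)
  delta <- 2 * (O - Y) / length(Y)
  grads <- vector("list", L)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(hs[[l]], delta), b = colSums(delta))
    if (l > 1)
      delta <- tcrossprod(delta, layers[[l]]$W) * lrelu_grad(as_[[l - 1]], slope)
  }
  list(f = f, grads = grads)
}

par_flatten <- function(layers)
  unlist(lapply(layers, function(l) c(l$W, l$b)), use.names = FALSE)

par_unflatten <- function(flat, template) {
  pos <- 0L
  out <- template
  for (l in seq_along(template)) {
    nw <- length(template[[l]]$W)
    nb <- length(template[[l]]$b)
    out[[l]]$W[] <- flat[pos + seq_len(nw)]
    out[[l]]$b <- flat[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  out
}

# One line search along direction d with quadratic/cubic interpolation and
# extrapolation (Wolfe-style): shrink by cubic fit when the Armijo bound
# fails, extend while the directional slope stays strongly negative.
# Returns NULL on failure, else the accepted point with f and g.
line_search_qc <- function(w, f0, s0, d, fg, a_init, max_evals = 5) {
  a <- a_init
  best <- NULL
  a_prev <- 0; f_prev <- f0; s_prev <- s0
  for (k in seq_len(max_evals)) {
    r <- fg(w + a * d)
    sa <- sum(r$g * d)
    armijo <- is.finite(r$f) && r$f <= f0 + 1e-4 * a * s0
    if (armijo && (is.null(best) || r$f < best$f))
      best <- list(a = a, f = r$f, g = r$g)
    if (armijo && abs(sa) <= 0.5 * abs(s0)) break      # strong Wolfe: done
    if (!armijo || r$f >= f_prev) {
      # overshoot: cubic interpolation on [a_prev, a]
      h <- a - a_prev
      dd <- s_prev + sa - 3 * (r$f - f_prev) / h
      rad <- dd^2 - s_prev * sa
      a_new <- if (is.finite(rad) && rad > 0) {
        a - h * (sa + sqrt(rad) - dd) / (sa - s_prev + 2 * sqrt(rad))
      } else (a_prev + a) / 2
      if (!is.finite(a_new) || a_new <= a_prev || a_new >= a)
        a_new <- (a_prev + a) / 2
      a <- a_new
    } else {
      # still descending steeply: extrapolate
      a_prev <- a; f_prev <- r$f; s_prev <- sa
      a <- a * 2
    }
  }
  best
}

# Polak-Ribiere conjugate-gradient run on one block, capped at `max_ls`
# line searches. fg(w) -> list(f, g). Never returns a point worse than the
# start. `a_init` warm-starts the first step size (and the last accepted
# size is returned for the next block).
cg_run <- function(w, fg, max_ls = 3, a_init = NULL, ls_evals = 5) {
  r <- fg(w)
  f <- r$f; g <- r$g
  if (!all(is.finite(g))) stop("non-finite gradient in conjugate-gradient update")
  gnorm2 <- sum(g * g)
  if (gnorm2 == 0) return(list(w = w, f = f, evals = 1L, a_last = a_init))
  d <- -g
  if (is.null(a_init)) a_init <- 1 / (1 + sqrt(gnorm2))
  a_last <- a_init
  w_best <- w; f_best <- f
  evals <- 1L
  for (ls in seq_len(max_ls)) {
    s0 <- sum(g * d)
    if (s0 >= 0) { d <- -g; s0 <- -sum(g * g) }
    ok <- line_search_qc(w, f, s0, d, fg, a_last, max_evals = ls_evals)
    evals <- evals + ls_evals
    if (is.null(ok)) break
    w <- w + ok$a * d
    f <- ok$f
    g_new <- ok$g
    if (f < f_best) { f_best <- f; w_best <- w }
    beta <- max(0, sum(g_new * (g_new - g)) / sum(g * g))
    d <- -g_new + beta * d
    g <- g_new
    a_last <- min(max(ok$a, 1e-10), 1e6)
    if (sum(g * g) < 1e-20) break
  }
  list(w = w_best, f = f_best, evals = evals, a_last = a_last)
}

#' One conjugate-gradient block update
#'
#' Minimizes the block MSE over all current weights with Polak-Ribiere
#' conjugate-gradient directions and at most `line_searches` line searches.
#' The block loss never increases (the best visited point is kept).
#'
#' @param model a `dnn_model` whose normalizers are already applied to the
#'   data (x and y z-scored).
#' @param x,y z-scored block input (T x d0) and target (T x D) matrices.
#' @param line_searches line-search cap (default 3).
#' @return The updated `dnn_model`.
#' @export
cg_block_update <- function(model, x, y, line_searches = 3, a_init = NULL) {
  if (nrow(x) == 0) stop("empty block")
  template <- model$layers
  fg <- function(w) {
    lay <- par_unflatten(w, template)
    r <- dnn_loss_grad(lay, model$slope, x, y)
    list(f = r$f, g = par_flatten(r$grads))
  }
  res <- cg_run(par_flatten(template), fg, max_ls = line_searches,
                a_init = a_init)
  model$layers <- par_unflatten(res$w, template)
  attr(model, "a_last") <- res$a_last
  model
}

#' Training configuration
#'
#' @param train_frac,val_frac,test_frac item-level split fractions
#'   (defaults 0.90/0.05/0.05; must sum to 1). Ties in item counts are
#'   resolved toward validation.
#' @param patience epochs without validation improvement before a stage
#'   stops (default 20).
#' @param min_delta smallest validation-MSE decrease that counts as an
#'   improvement for the patience rule (default 1e-4; best weights are
#'   still tracked at full precision).
#' @param blocks_per_epoch number of shuffled blocks per epoch (default 100).
#' @param line_searches conjugate-gradient line-search cap per block.
#' @param max_epochs safety bound per stage (default 500).
#' @param hidden_units,n_hidden architecture (default 3 hidden layers of
#'   200 units).
#' @param slope leaky-rectifier negative slope (default 0.01).
#' @param seed integer seed governing split, initialization and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(train_frac = 0.90, val_frac = 0.05,
                         test_frac = 0.05, patience = 20, min_delta = 1e-4,
                         blocks_per_epoch = 100, line_searches = 3,
                         max_epochs = 500, hidden_units = 200,
                         n_hidden = 3, slope = 0.01, seed = 1) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stop("split fractions must sum to 1")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, patience = patience,
                 min_delta = min_delta,
                 blocks_per_epoch = blocks_per_epoch,
                 line_searches = line_searches, max_epochs = max_epochs,
                 hidden_units = hidden_units, n_hidden = n_hidden,
                 slope = slope, seed = seed), class = "train_config")
}

# item-level split: frames of one item never straddle subsets
split_items <- function(n_items, cfg) {
  if (n_items < 3) stop("need at least 3 items for the train/val/test split")
  perm <- sample.int(n_items)
  n_train <- floor(cfg$train_frac * n_items)
  n_rest <- n_items - n_train
  n_val <- ceiling(n_rest / 2)          # ties toward validation
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_rest - n_val)]))
}

#' Layer-wise DNN training for articulatory-to-acoustic mapping
#'
#' Trains a feed-forward network by successive layer addition: stage 1
#' trains input-hidden-output; each later stage keeps the trained hidden
#' layers, inserts a freshly initialized hidden layer, replaces the output
#' layer, and fine-tunes the whole network. Every stage runs epochs of
#' shuffled-frame blocks minimized by [cg_block_update()], stopping when
#' the validation MSE has not improved for `cfg$patience` epochs (best
#' weights restored). Items are split 90/5/5 into train/validation/test;
#' input and output normalizers are fitted on the training items only.
#'
#' @param pairs list of items, each a list with `x` (T_i x d stacked
#'   articulatory frames) and `y` (T_i x D mel-cepstral frames); silence
#'   frames should already be removed.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return List with `model` (a `dnn_model` carrying the normalizers) and
#'   `report` (a `train_report`: per-stage epoch curves, best epochs, the
#'   item split, and final test MSE on held-out items).
#' @export
train_layerwise <- function(pairs, cfg = train_config(), verbose = FALSE) {
  set.seed(cfg$seed)
  n_items <- length(pairs)
  split <- split_items(n_items, cfg)
  d_in <- ncol(pairs[[1]]$x)
  d_out <- ncol(pairs[[1]]$y)

  bindx <- function(ids, what) do.call(rbind, lapply(pairs[ids],
                                                     function(p) p[[what]]))
  Xtr_raw <- bindx(split$train, "x"); Ytr_raw <- bindx(split$train, "y")
  in_norm <- fit_normalizer(Xtr_raw)
  out_norm <- fit_normalizer(Ytr_raw)
  zx <- function(M) apply_normalizer(in_norm, M)
  zy <- function(M) apply_normalizer(out_norm, M)
  Xtr <- zx(Xtr_raw); Ytr <- zy(Ytr_raw)
  Xval <- zx(bindx(split$val, "x")); Yval <- zy(bindx(split$val, "y"))
  has_test <- length(split$test) > 0
  if (has_test) { Xte <- zx(bindx(split$test, "x"))
                  Yte <- zy(bindx(split$test, "y")) }
  n_tr <- nrow(Xtr)

  h <- cfg$hidden_units
  layers <- list(init_layer(d_in, h), init_layer(h, d_out))
  stages <- vector("list", cfg$n_hidden)

  for (stage in seq_len(cfg$n_hidden)) {
    if (stage > 1) {
      hidden <- layers[seq_len(stage - 1)]
      layers <- c(hidden, list(init_layer(h, h), init_layer(h, d_out)))
    }
    best_val <- Inf; best_layers <- layers; best_epoch <- 0L
    hist <- data.frame(epoch = integer(), train_mse = numeric(),
                       val_mse = numeric())
    model <- new_dnn_model(layers, cfg$slope)
    a_warm <- NULL
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      bounds <- floor(seq(0, n_tr, length.out = cfg$blocks_per_epoch + 1))
      for (bl in seq_len(cfg$blocks_per_epoch)) {
        rows <- ord[(bounds[bl] + 1):bounds[bl + 1]]
        if (length(rows) == 0) next
        model <- cg_block_update(model, Xtr[rows, , drop = FALSE],
                                 Ytr[rows, , drop = FALSE],
                                 cfg$line_searches, a_init = a_warm)
        a_warm <- attr(model, "a_last")
      }
      tr_loss <- mse_loss(dnn_forward_z(model$layers, cfg$slope, Xtr), Ytr)
      val_loss <- mse_loss(dnn_forward_z(model$layers, cfg$slope, Xval), Yval)
      hist <- rbind(hist, data.frame(epoch = epoch, train_mse = tr_loss,
                                     val_mse = val_loss))
      if (verbose)
        message(sprintf("stage %d epoch %3d train %.5f val %.5f",
                        stage, epoch, tr_loss, val_loss))
      if (val_loss < best_val - cfg$min_delta) best_epoch <- epoch
      if (val_loss < best_val) {
        best_val <- val_loss; best_layers <- model$layers
      }
      if (epoch - best_epoch >= cfg$patience) break
    }
    layers <- best_layers
    stages[[stage]] <- list(history = hist, best_epoch = best_epoch,
                            best_val = best_val,
                            n_layers = length(layers) - 1L)
  }

  model <- new_dnn_model(layers, cfg$slope, in_norm, out_norm)
  test_mse <- if (has_test)
    mse_loss(dnn_forward_z(layers, cfg$slope, Xte), Yte) else NA_real_
  report <- structure(list(stages = stages, split = split,
                           test_mse = test_mse, config = cfg),
                      class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat("<train_report>\n")
  for (s in seq_along(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  stage %d: %d epochs, best val MSE %.5f (epoch %d)\n",
                s, nrow(st$history), st$best_val, st$best_epoch))
  }
  cat(sprintf("  held-out test MSE (z-scored): %.5f\n", x$test_mse))
  invisible(x)
}

#' Network forward pass
#'
#' Maps stacked articulatory frames to mel-cepstral frames: z-scores the
#' input with the model's input normalizer, runs the fully connected
#' leaky-rectifier network, and de-z-scores the linear output.
#'
#' @param model a trained `dnn_model`.
#' @param stacked T x d0 matrix of stacked articulatory frames (raw scale).
#' @return T x D matrix of mel-cepstral coefficients.
#' @export
dnn_predict <- function(model, stacked) {
  stacked <- as.matrix(stacked)
  if (ncol(stacked) != nrow(model$layers[[1]]$W))
    stop("input has ", ncol(stacked), " columns; model expects ",
         nrow(model$layers[[1]]$W))
  X <- if (is.null(model$in_norm)) stacked
       else apply_normalizer(model$in_norm, stacked)
  O <- dnn_forward_z(model$layers, model$slope, X)
  if (is.null(model$out_norm)) O else invert_normalizer(model$out_norm, O)
}

#' Evaluate an articulatory-to-acoustic mapping
#'
#' @param model a trained `dnn_model`.
#' @param pairs list of items with raw-scale `x` and `y` as in
#'   [train_layerwise()].
#' @return List with `mse` (frame-averaged z-scored MSE) and `mcd_db`
#'   (mel-cepstral distortion of the de-normalized predictions).
#' @export
evaluate_mapping <- function(model, pairs) {
  if (length(pairs) == 0) stop("no evaluation pairs")
  X <- do.call(rbind, lapply(pairs, `[[`, "x"))
  Y <- do.call(rbind, lapply(pairs, `[[`, "y"))
  pred <- dnn_predict(model, X)
  Yz <- if (is.null(model$out_norm)) Y else apply_normalizer(model$out_norm, Y)
  predz <- if (is.null(model$out_norm)) pred
           else apply_normalizer(model$out_norm, pred)
  list(mse = mse_loss(predz, Yz), mcd_db = mel_cepstral_distortion(pred, Y))
}

#' Serialize / load a trained network as text
#'
#' Self-describing text container: layer sizes, activation slope,
#' normalizer statistics and full-precision weights.
#'
#' @param model a `dnn_model`.
#' @param path file path.
#' @return `path` invisibly, or the restored `dnn_model`.
#' @export
write_dnn <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sizes <- c(nrow(model$layers[[1]]$W),
             vapply(model$layers, function(l) ncol(l$W), 0L))
  wl <- function(...) writeLines(sprintf(...), con)
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  wl("# emasynth dnn v1")
  wl("sizes\t%s", paste(sizes, collapse = "\t"))
  wl("slope\t%.17g", model$slope)
  for (nm in c("in_norm", "out_norm")) {
    nrm <- model[[nm]]
    if (!is.null(nrm)) {
      wl("%s_mean\t%s", nm, num(nrm$mean))
      wl("%s_sd\t%s", nm, num(nrm$sd))
    }
  }
  for (l in seq_along(model$layers)) {
    wl("W%d\t%s", l, num(model$layers[[l]]$W))
    wl("b%d\t%s", l, num(model$layers[[l]]$b))
  }
  invisible(path)
}

#' @rdname write_dnn
#' @export
read_dnn <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- strsplit(lines, "\t")
  keys <- vapply(kv, `[[`, "", 1)
  val <- function(k) as.numeric(kv[[match(k, keys)]][-1])
  sizes <- as.integer(val("sizes"))
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L))
    layers[[l]] <- list(W = matrix(val(paste0("W", l)), sizes[l], sizes[l + 1]),
                        b = val(paste0("b", l)))
  mknorm <- function(nm) {
    if (!paste0(nm, "_mean") %in% keys) return(NULL)
    structure(list(mean = val(paste0(nm, "_mean")),
                   sd = val(paste0(nm, "_sd"))), class = "normalizer")
  }
  new_dnn_model(layers, val("slope"), mknorm("in_norm"), mknorm("out_norm"))
}
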