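## Unpaired FLIM -> false-histology translation: two generators and two
## patch discriminators trained with a least-squares adversarial loss
## plus an L1 cycle-consistency penalty. The networks are deliberately
## small 3x3 convolutional stacks whose width scales with the config so
## a CPU can train desk-scale models; forward/backward passes are
## written out explicitly.

## ---- minimal conv-net machinery ------------------------------------

## zero-padded shift: out[i, j] = m[i + di, j + dj]
shift2 <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + di):min(nr, nr + di)
  cs <- max(1, 1 + dj):min(nc, nc + dj)
  if (length(rs) && length(cs))
    out[rs - di, cs - dj] <- m[rs, cs]
  out
}

conv_forward <- function(x, W, b) {
  dW <- dim(W)  # (3, 3, cin, cout)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], dW[4]))
  for (co in seq_len(dW[4])) {
    acc <- matrix(b[co], d[1], d[2])
    for (ci in seq_len(dW[3])) {
      xm <- x[, , ci]
      for (di in -1:1) for (dj in -1:1) {
        w <- W[di + 2, dj + 2, ci, co]
        if (w != 0) acc <- acc + w * shift2(xm, di, dj)
      }
    }
    out[, , co] <- acc
  }
  out
}

conv_backward <- function(x, W, dy) {
  dW <- array(0, dim = dim(W))
  db <- numeric(dim(W)[4])
  dx <- array(0, dim = dim(x))
  for (co in seq_len(dim(W)[4])) {
    g <- dy[, , co]
    db[co] <- sum(g)
    for (ci in seq_len(dim(W)[3])) {
      xm <- x[, , ci]
      for (di in -1:1) for (dj in -1:1) {
        dW[di + 2, dj + 2, ci, co] <- sum(shift2(xm, di, dj) * g)
        dx[, , ci] <- dx[, , ci] + W[di + 2, dj + 2, ci, co] * shift2(g, -di, -dj)
      }
    }
  }
  list(dW = dW, db = db, dx = dx)
}

act_forward <- function(z, act) {
  switch(act,
         linear = z,
         relu = pmax(z, 0),
         lrelu = ifelse(z > 0, z, 0.2 * z),
         sigmoid = 1 / (1 + exp(-z)))
}

act_backward <- function(z, a, act) {
  switch(act,
         linear = array(1, dim = dim(z)),
         relu = (z > 0) * 1,
         lrelu = ifelse(z > 0, 1, 0.2),
         sigmoid = a * (1 - a))
}

new_conv_net <- function(widths, acts, gain = 0.05) {
  # widths: channel counts c(cin, h1, ..., cout); acts: length-1 shorter
  layers <- vector("list", length(widths) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(
      W = array(stats::rnorm(9 * widths[l] * widths[l + 1], 0, gain),
                dim = c(3, 3, widths[l], widths[l + 1])),
      b = numeric(widths[l + 1]),
      act = acts[l])
  }
  layers
}

net_forward <- function(net, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(net)) else NULL
  a <- x
  for (l in seq_along(net)) {
    z <- conv_forward(a, net[[l]]$W, net[[l]]$b)
    anew <- act_forward(z, net[[l]]$act)
    if (keep) caches[[l]] <- list(x = a, z = z, a = anew)
    a <- anew
  }
  if (keep) list(out = a, caches = caches) else a
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  d <- dout
  for (l in rev(seq_along(net))) {
    dz <- d * act_backward(caches[[l]]$z, caches[[l]]$a, net[[l]]$act)
    g <- conv_backward(caches[[l]]$x, net[[l]]$W, dz)
    grads[[l]] <- list(dW = g$dW, db = g$db)
    d <- g$dx
  }
  list(grads = grads, dx = d)
}

## Adam over a list of layer parameter sets
adam_init <- function(net) {
  lapply(net, function(l) list(mW = array(0, dim = dim(l$W)),
                               vW = array(0, dim = dim(l$W)),
                               mb = numeric(length(l$b)),
                               vb = numeric(length(l$b))))
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(net)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    net[[l]]$W <- net[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
    net[[l]]$b <- net[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

## ---- model surface -------------------------------------------------

#' Unpaired translation model
#'
#' The four networks of the cycle-consistent translation stage: the
#' forward generator `G_FH` (FLIM-domain to histology-domain), the
#' reverse generator `G_HF`, and the discriminators `D_FH`, `D_HF` of
#' the two mappings, plus the cycle weight `lambda`.
#'
#' @param width hidden channel width of generators/discriminators.
#' @param lambda weight of the cycle-consistency term (default 10, the
#'   original recipe's value).
#' @param channels image channels (3).
#' @param image_size input side length the model was built for.
#' @param seed integer; fixes the weight initialisation.
#' @return object of class `translation_model`.
#' @export
translation_model <- function(width = 8L, lambda = 10, channels = 3L,
                              image_size = 256L, seed = 1L) {
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  with_seed(seed, {
    gen <- function() new_conv_net(c(channels, width, width, channels),
                                   c("relu", "relu", "sigmoid"))
    dis <- function() new_conv_net(c(channels, width, 1L),
                                   c("lrelu", "linear"))
    structure(list(G_FH = gen(), G_HF = gen(), D_FH = dis(), D_HF = dis(),
                   lambda = lambda, channels = as.integer(channels),
                   image_size = as.integer(image_size)),
              class = "translation_model")
  })
}

#' @export
print.translation_model <- function(x, ...) {
  np <- function(net) sum(vapply(net, function(l) length(l$W) + length(l$b),
                                 numeric(1)))
  cat(sprintf("Cycle-consistent translation model (lambda = %g)\n", x$lambda))
  cat(sprintf("  generators: %d + %d params; discriminators: %d + %d params\n",
              np(x$G_FH), np(x$G_HF), np(x$D_FH), np(x$D_HF)))
  cat(sprintf("  built for %d x %d x %d inputs\n",
              x$image_size, x$image_size, x$channels))
  invisible(x)
}

as_image3 <- function(img, channels = 3L) {
  if (!is_rgb(img)) img <- grey_to_rgb(img)
  if (dim(img)[3] != channels)
    stop_invalid("expected %d channels, got %d", channels, dim(img)[3])
  img
}

## least-squares adversarial terms
lsgan_d <- function(d_real, d_fake) mean((d_real - 1)^2) + mean(d_fake^2)
lsgan_g <- function(d_fake) mean((d_fake - 1)^2)

#' Cycle-consistent adversarial objective
#'
#' Evaluates the overall translation objective
#' `L = L_FH + L_HF + lambda * L_cyc` on two unpaired batches:
#' the least-squares adversarial losses of the two generator/
#' discriminator pairs and the L1 cycle-consistency term (both
#' directions).
#'
#' @param model [translation_model], or a list with generator/
#'   discriminator functions for testing.
#' @param batch_F,batch_H non-empty lists of images in `[0, 1]` from the
#'   FLIM-rendering and histology domains.
#' @return list with `total`, `adv_FH`, `adv_HF`, `cyc`.
#' @export
cycle_objective <- function(model, batch_F, batch_H) {
  if (!length(batch_F) || !length(batch_H)) stop_invalid("empty batch")
  gf <- model_fun(model, "G_FH"); gh <- model_fun(model, "G_HF")
  df <- model_fun(model, "D_FH"); dh <- model_fun(model, "D_HF")
  ch <- model$channels %||% 3L
  batch_F <- lapply(batch_F, as_image3, channels = ch)
  batch_H <- lapply(batch_H, as_image3, channels = ch)
  avg <- function(batch, f) mean(vapply(batch, f, numeric(1)))
  # least-squares adversarial loss of each mapping: real -> 1, fake -> 0
  adv_FH <- avg(batch_H, function(y) mean((df(y) - 1)^2)) +
    avg(batch_F, function(x) mean(df(gf(x))^2))
  adv_HF <- avg(batch_F, function(x) mean((dh(x) - 1)^2)) +
    avg(batch_H, function(y) mean(dh(gh(y))^2))
  cyc <- avg(batch_F, function(x) mean(abs(gh(gf(x)) - x))) +
    avg(batch_H, function(y) mean(abs(gf(gh(y)) - y)))
  lambda <- model$lambda %||% 10
  list(total = adv_FH + adv_HF + lambda * cyc,
       adv_FH = adv_FH, adv_HF = adv_HF, cyc = cyc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## resolve a component of either a translation_model or a plain list of
## functions (test stubs)
model_fun <- function(model, name) {
  comp <- model[[name]]
  if (is.function(comp)) return(comp)
  function(x) net_forward(comp, x)
}

#' Translation training configuration
#'
#' Defaults follow the training setup of the translation stage: batch
#' size 16 and 50 epochs, with the original recipe's Adam optimiser
#' (learning rate 2e-4, beta1 0.5).
#'
#' @param batch_size images per update (default 16).
#' @param epochs passes over the FLIM domain (default 50).
#' @param image_size model input side; inputs are cropped/resized to it.
#' @param width hidden channel width (depth scale) of the networks.
#' @param lambda cycle weight.
#' @param learning_rate Adam learning rate.
#' @param mask_histology background-mask histology patches before
#'   training (default TRUE).
#' @param seed integer seed fixing shuffling, cropping and
#'   initialisation.
#' @return list of class `translate_config`.
#' @export
translate_config <- function(batch_size = 16L, epochs = 50L,
                             image_size = 256L, width = 8L, lambda = 10,
                             learning_rate = 2e-4, mask_histology = TRUE,
                             seed = 1L) {
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  if (epochs < 1) stop_invalid("epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 image_size = as.integer(image_size),
                 width = as.integer(width), lambda = lambda,
                 learning_rate = learning_rate,
                 mask_histology = isTRUE(mask_histology),
                 seed = as.integer(seed)),
            class = "translate_config")
}

#' Train the unpaired translation model
#'
#' Trains generators and discriminators on unpaired FLIM renderings and
#' histology patches. FLIM images are shuffled regardless of wavelength;
#' each histology patch is cropped at a random position and size (from
#' the model input size up to the full patch) and resized to the model
#' input size, optionally after background masking. Each batch performs
#' a discriminator update (least-squares real/fake targets) followed by
#' a generator update (adversarial + cycle terms). Training is
#' deterministic given the seed.
#'
#' @param flim_images list of FLIM-domain images in `[0, 1]`.
#' @param histo_patches list of histology images in `[0, 1]`.
#' @param config [translate_config()].
#' @return trained [translation_model()] with a `history` attribute:
#'   data.frame of per-epoch mean generator and discriminator losses.
#' @export
train_translation <- function(flim_images, histo_patches,
                              config = translate_config()) {
  if (!length(flim_images) || !length(histo_patches))
    stop_invalid("need at least one image per domain")
  chan <- vapply(flim_images, n_channels, integer(1))
  if (length(unique(chan)) != 1L)
    stop_invalid("FLIM-domain images have inconsistent channel counts")
  N <- config$image_size
  with_seed(config$seed, {
    model <- translation_model(config$width, config$lambda,
                               image_size = N,
                               seed = sample.int(1e6, 1))
    st <- list(G_FH = adam_init(model$G_FH), G_HF = adam_init(model$G_HF),
               D_FH = adam_init(model$D_FH), D_HF = adam_init(model$D_HF))
    t_adam <- 0L
    prep_histo <- function(img) {
      img <- as_image3(img)
      d <- dim(img)[1:2]
      if (config$mask_histology) {
        msk <- tryCatch(background_mask(img), warning = function(w) NULL)
        if (!is.null(msk)) img <- apply_mask(img, msk)
      }
      cs <- if (min(d) > N) sample(N:min(d), 1) else min(d, N)
      y0 <- if (d[1] > cs) sample.int(d[1] - cs + 1L, 1) - 1L else 0L
      x0 <- if (d[2] > cs) sample.int(d[2] - cs + 1L, 1) - 1L else 0L
      patch <- img[y0 + seq_len(min(cs, d[1])), x0 + seq_len(min(cs, d[2])), ,
                   drop = FALSE]
      if (!all(dim(patch)[1:2] == N)) patch <- resize_bilinear(patch, N, N)
      patch
    }
    prep_flim <- function(img) {
      img <- as_image3(img)
      if (!all(dim(img)[1:2] == N)) img <- resize_bilinear(img, N, N)
      img
    }
    history <- data.frame(epoch = integer(0), g_loss = numeric(0),
                          d_loss = numeric(0))
    nF <- length(flim_images)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nF)
      g_losses <- d_losses <- c()
      for (b0 in seq(1, nF, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, nF)]
        xs <- lapply(flim_images[idx], prep_flim)
        ys <- lapply(sample(histo_patches, length(idx), replace = TRUE),
                     prep_histo)
        upd <- train_batch(model, st, xs, ys, config$learning_rate,
                           t_adam + 1L)
        model <- upd$model; st <- upd$state; t_adam <- t_adam + 1L
        g_losses <- c(g_losses, upd$g_loss)
        d_losses <- c(d_losses, upd$d_loss)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, g_loss = mean(g_losses),
                                  d_loss = mean(d_losses)))
    }
    attr(model, "history") <- history
    model
  })
}

## one discriminator + one generator update on a batch
train_batch <- function(model, st, xs, ys, lr, t) {
  nb <- length(xs)
  zero_grads <- function(net) lapply(net, function(l)
    list(dW = array(0, dim = dim(l$W)), db = numeric(length(l$b))))
  add_grads <- function(a, g, w = 1) {
    for (l in seq_along(a)) {
      a[[l]]$dW <- a[[l]]$dW + w * g[[l]]$dW
      a[[l]]$db <- a[[l]]$db + w * g[[l]]$db
    }
    a
  }

  ## --- discriminators: push real -> 1, fake -> 0
  gD_FH <- zero_grads(model$D_FH); gD_HF <- zero_grads(model$D_HF)
  d_loss <- 0
  for (i in seq_len(nb)) {
    x <- xs[[i]]; y <- ys[[i]]
    fake_h <- net_forward(model$G_FH, x)
    fake_f <- net_forward(model$G_HF, y)
    for (pair in list(list(net = "D_FH", real = y, fake = fake_h,
                           acc = quote(gD_FH)),
                      list(net = "D_HF", real = x, fake = fake_f,
                           acc = quote(gD_HF)))) {
      fr <- net_forward(model[[pair$net]], pair$real, keep = TRUE)
      ff <- net_forward(model[[pair$net]], pair$fake, keep = TRUE)
      d_loss <- d_loss + (mean((fr$out - 1)^2) + mean(ff$out^2)) / (2 * nb)
      dr <- 2 * (fr$out - 1) / length(fr$out) / (2 * nb)
      df <- 2 * ff$out / length(ff$out) / (2 * nb)
      br <- net_backward(model[[pair$net]], fr$caches, dr)
      bf <- net_backward(model[[pair$net]], ff$caches, df)
      g <- add_grads(add_grads(zero_grads(model[[pair$net]]), br$grads),
                     bf$grads)
      if (pair$net == "D_FH") gD_FH <- add_grads(gD_FH, g)
      else gD_HF <- add_grads(gD_HF, g)
    }
  }
  a <- adam_step(model$D_FH, gD_FH, st$D_FH, lr, t)
  model$D_FH <- a$net; st$D_FH <- a$state
  a <- adam_step(model$D_HF, gD_HF, st$D_HF, lr, t)
  model$D_HF <- a$net; st$D_HF <- a$state

  ## --- generators: adversarial (fake -> 1) + cycle L1, both directions
  gG_FH <- zero_grads(model$G_FH); gG_HF <- zero_grads(model$G_HF)
  lambda <- model$lambda
  g_loss <- 0
  for (i in seq_len(nb)) {
    x <- xs[[i]]; y <- ys[[i]]
    # forward cycle: x -> fake_h -> rec_x
    fh <- net_forward(model$G_FH, x, keep = TRUE)
    dfh <- net_forward(model$D_FH, fh$out, keep = TRUE)
    rec <- net_forward(model$G_HF, fh$out, keep = TRUE)
    adv <- mean((dfh$out - 1)^2)
    cycl <- mean(abs(rec$out - x))
    g_loss <- g_loss + (adv + lambda * cycl) / (2 * nb)
    # backprop adv through D (frozen) into fake_h
    d_adv <- 2 * (dfh$out - 1) / length(dfh$out)
    back_d <- net_backward(model$D_FH, dfh$caches, d_adv)
    # backprop cycle through G_HF into fake_h
    d_cyc_out <- lambda * sign(rec$out - x) / length(rec$out)
    back_hf <- net_backward(model$G_HF, rec$caches, d_cyc_out)
    gG_HF <- add_grads(gG_HF, back_hf$grads, 1 / (2 * nb))
    d_fake <- (back_d$dx + back_hf$dx)
    back_fh <- net_backward(model$G_FH, fh$caches, d_fake)
    gG_FH <- add_grads(gG_FH, back_fh$grads, 1 / (2 * nb))
    # reverse cycle: y -> fake_f -> rec_y
    hf <- net_forward(model$G_HF, y, keep = TRUE)
    dhf <- net_forward(model$D_HF, hf$out, keep = TRUE)
    rec2 <- net_forward(model$G_FH, hf$out, keep = TRUE)
    adv2 <- mean((dhf$out - 1)^2)
    cyc2 <- mean(abs(rec2$out - y))
    g_loss <- g_loss + (adv2 + lambda * cyc2) / (2 * nb)
    d_adv2 <- 2 * (dhf$out - 1) / length(dhf$out)
    back_d2 <- net_backward(model$D_HF, dhf$caches, d_adv2)
    d_cyc2 <- lambda * sign(rec2$out - y) / length(rec2$out)
    back_fh2 <- net_backward(model$G_FH, rec2$caches, d_cyc2)
    gG_FH <- add_grads(gG_FH, back_fh2$grads, 1 / (2 * nb))
    d_fake2 <- (back_d2$dx + back_fh2$dx)
    back_hf2 <- net_backward(model$G_HF, hf$caches, d_fake2)
    gG_HF <- add_grads(gG_HF, back_hf2$grads, 1 / (2 * nb))
  }
  a <- adam_step(model$G_FH, gG_FH, st$G_FH, lr, t)
  model$G_FH <- a$net; st$G_FH <- a$state
  a <- adam_step(model$G_HF, gG_HF, st$G_HF, lr, t)
  model$G_HF <- a$net; st$G_HF <- a$state
  list(model = model, state = st, g_loss = g_loss, d_loss = d_loss)
}

#' Translate a FLIM rendering to a false histology image
#'
#' Applies the forward generator; when an intensity mask is supplied the
#' output is multiplied by it pixel-wise, suppressing hallucinated
#' content in zero-signal (filtered) areas. Input is resized to the
#' model's input size if needed and the output is returned at the
#' original size.
#'
#' @param model [translation_model()] or any translator accepted by
#'   [as_translator()].
#' @param flim_rgb image in `[0, 1]`.
#' @param intensity_mask optional binary matrix at the input's spatial
#'   size.
#' @return translated image, same shape as the input.
#' @export
translate_image <- function(model, flim_rgb, intensity_mask = NULL) {
  f <- as_translator(model)
  out <- f(flim_rgb)
  if (!is.null(intensity_mask)) {
    if (!identical(dim(intensity_mask),
                   if (is_rgb(out)) dim(out)[1:2] else dim(out)))
      stop_invalid("intensity mask shape mismatch")
    out <- apply_mask(out, intensity_mask)
  }
  out
}

#' Translator interface
#'
#' The registration stage depends only on a translator function
#' `f(image) -> image`, so trained models and simple baselines are
#' interchangeable. Accepted inputs: a function; a
#' [translation_model()]; the strings `"identity"` (pass-through) or
#' `"equalise"` (greyscale contrast booster).
#'
#' @param x translator specification.
#' @return function mapping an image to an image of the same size.
#' @export
as_translator <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, "translation_model")) {
    model <- x
    return(function(img) {
      d <- if (is_rgb(img)) dim(img)[1:2] else dim(img)
      inp <- as_image3(img, model$channels)
      N <- model$image_size
      resized <- !all(d == N)
      if (resized) inp <- resize_bilinear(inp, N, N)
      out <- net_forward(model$G_FH, inp)
      if (resized) out <- resize_bilinear(out, d[1], d[2])
      if (!is_rgb(img)) rgb_to_grey(out) else out
    })
  }
  if (is.character(x)) {
    return(switch(x,
                  identity = function(img) img,
                  equalise = function(img) {
                    g <- equalise(rgb_to_grey(img))
                    if (is_rgb(img)) grey_to_rgb(g) else g
                  },
                  stop_invalid("unknown translator '%s'", x)))
  }
  stop_invalid("cannot interpret translator")
}

#' Save / load a translation model
#'
#' @param model [translation_model()].
#' @param path checkpoint file path.
#' @return the model (reader) or `path` invisibly (writer).
#' @export
write_translation_model <- function(model, path) {
  stopifnot(inherits(model, "translation_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_translation_model
#' @export
read_translation_model <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "translation_model")) stop_invalid("not a model checkpoint")
  x
}
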