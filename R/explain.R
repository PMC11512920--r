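#' Perturb one frame of an image sequence over electrode super-pixels
#'
#' Draws `N` binary interpretable instances `z' in {0,1}^d'` (one bit per
#' super-pixel, independent fair coins; the all-ones vector is always sample
#' 1) and builds the perturbed versions of the chosen frame: pixels of
#' switched-off super-pixels are set to `fill` in every layer, the other 29
#' frames of the sequence are left untouched.
#'
#' @param sequence `mesh x mesh x in_ch x T` array.
#' @param frame_idx 1-based frame index.
#' @param mask a [build_feature_mask()] result.
#' @param N number of perturbed samples (>= 2).
#' @param seed integer seed.
#' @param fill replacement value for switched-off pixels (0 = absent CFS).
#' @return list with `designs` (`N x d'` 0/1 matrix) and `frames`
#'   (`mesh x mesh x in_ch x N` perturbed frame stack).
#' @export
perturb_frame <- function(sequence, frame_idx, mask, N, seed = 1, fill = 0) {
  d <- dim(sequence)
  if (frame_idx < 1 || frame_idx > d[4]) stop("frame_idx out of range")
  if (N < 2) stop("need N >= 2 perturbed samples")
  labs <- sort(setdiff(unique(as.vector(unclass(mask))), 0L))
  if (length(labs) == 0) stop("empty feature mask")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  Z <- matrix(stats::rbinom(N * length(labs), 1, 0.5), N, length(labs))
  Z[1, ] <- 1L
  list(designs = Z,
       frames = apply_designs(sequence[, , , frame_idx, drop = FALSE], mask,
                              Z, labs, fill))
}

# pixel -> design-column lookup (label 0 outside the hull maps to a
# constant keep-on column), replicated across image channels
mask_pixel_index <- function(mask, labs, n_ch) {
  midx <- match(as.vector(unclass(mask)), labs)  # NA outside hull
  midx[is.na(midx)] <- 0L
  rep.int(midx, n_ch) + 1L
}

# perturbed frames as a flat (mesh*mesh*nc x N) matrix: one indexing pass
perturb_flat <- function(frame_vec, pix_idx, Z, fill = 0) {
  keep <- t(cbind(1L, Z))[pix_idx, , drop = FALSE]
  frame_vec * keep + fill * (1 - keep)
}

# build perturbed frame stack from a design matrix
apply_designs <- function(frame, mask, Z, labs, fill = 0) {
  d <- dim(frame)
  mesh <- d[1]; nc <- d[3]
  pix_idx <- mask_pixel_index(mask, labs, nc)
  flat <- perturb_flat(as.numeric(frame), pix_idx, Z, fill)
  array(flat, dim = c(mesh, mesh, nc, nrow(Z)))
}

#' Exponential proximity kernel on Euclidean distance
#'
#' `pi_x = exp(-D^2 / width^2)` with `D` the Euclidean distance between the
#' original and the perturbed frame in pixel space.
#'
#' @param x_frame,z_frame equal-shaped numeric arrays.
#' @param width kernel width (> 0).
#' @return weight in (0, 1\].
#' @export
kernel_weight <- function(x_frame, z_frame, width) {
  if (width <= 0) stop("kernel width must be positive")
  if (!identical(dim(x_frame), dim(z_frame)) &&
      length(x_frame) != length(z_frame))
    stop("frame shapes differ")
  D2 <- sum((as.numeric(x_frame) - as.numeric(z_frame))^2)
  exp(-D2 / width^2)
}

# default kernel width: 0.25 * sqrt(d') on the binary design scale, mapped
# to pixel space through the RMS pixel mass of one average super-pixel, so
# switching off k super-pixels sits at binary distance ~sqrt(k)
default_kernel_width <- function(x_frame, d_prime) {
  sigma_sp <- sqrt(sum(as.numeric(x_frame)^2) / max(d_prime, 1))
  if (sigma_sp <= 0) sigma_sp <- 1
  0.25 * sqrt(d_prime) * sigma_sp
}

# per-frame CNN features of a sequence (eval mode), D x T
model_frame_features <- function(model, sequence) {
  cfg <- model$cfg
  nn_cnn_features_cpp(model$params, unclass(cfg), as.numeric(sequence),
                      dim(sequence)[4], FALSE)
}

#' Explain one frame with a feature-mask local surrogate
#'
#' Local interpretable explanation of the classifier score for one frame:
#' the frame is perturbed over electrode super-pixels ([perturb_frame()]),
#' the model is scored on every perturbed sequence (the LSTM is resumed from
#' the cached state before the perturbed frame, so only that frame is
#' re-encoded), samples are weighted by the exponential proximity kernel,
#' and a lasso surrogate is fitted to `design -> score`. Its coefficients,
#' indexed by super-pixel/electrode, are the local relevances.
#'
#' @param model a `cnn_lstm_model`, or any function
#'   `f(frames, frame_idx) -> scores` taking a `mesh x mesh x in_ch x N`
#'   stack of perturbed frames and returning one score per sample (the
#'   model-agnostic path used for oracle models).
#' @param sequence `mesh x mesh x in_ch x T` array.
#' @param frame_idx 1-based frame to explain.
#' @param mask a [build_feature_mask()].
#' @param N perturbed-sample count (study default 10,000).
#' @param lasso_penalty lasso `lambda` on the normalised score scale (the
#'   effective penalty is `lasso_penalty * sd(scores)`); the fixed default
#'   keeps explanations deterministic rather than re-tuned per frame.
#' @param seed integer seed.
#' @param class class whose probability is explained (`"dyslexic"` or
#'   `"control"`).
#' @param kernel_width proximity kernel width; `NULL` = default scale (see
#'   vignette).
#' @param fill value for switched-off pixels.
#' @param chunk_size samples scored per batch (memory bound).
#' @return numeric vector of `d'` coefficients (named by electrode), with
#'   attributes `intercept`, `fidelity` (weighted R^2 of the surrogate) and
#'   `loss` (weighted square loss).
#' @export
explain_frame <- function(model, sequence, frame_idx, mask, N = 10000,
                          lasso_penalty = 1e-3, seed = 1,
                          class = "dyslexic", kernel_width = NULL,
                          fill = 0, chunk_size = 1000) {
  labs <- sort(setdiff(unique(as.vector(unclass(mask))), 0L))
  d_prime <- length(labs)
  is_nn <- inherits(model, "cnn_lstm_model")
  if (is_nn) {
    cls <- match(match.arg(class, model$classes), model$classes)
    feats <- model_frame_features(model, sequence)
  } else if (!is.function(model)) {
    stop("model must be a cnn_lstm_model or a scoring function")
  }
  x_frame <- sequence[, , , frame_idx, drop = FALSE]
  if (is.null(kernel_width))
    kernel_width <- default_kernel_width(x_frame, d_prime)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  Z <- matrix(stats::rbinom(N * d_prime, 1, 0.5), N, d_prime)
  Z[1, ] <- 1L
  scores <- numeric(N)
  wts <- numeric(N)
  xf <- as.numeric(x_frame)
  pix_idx <- mask_pixel_index(mask, labs, dim(sequence)[3])
  for (s0 in seq(1, N, by = chunk_size)) {
    idx <- s0:min(s0 + chunk_size - 1, N)
    flat <- perturb_flat(xf, pix_idx, Z[idx, , drop = FALSE], fill)
    if (is_nn) {
      pr <- nn_score_perturbed_cpp(model$params, unclass(model$cfg), feats,
                                   flat, length(idx), frame_idx)
      scores[idx] <- pr[, cls]
    } else {
      scores[idx] <- model(array(flat, dim = c(dim(x_frame)[1:3], length(idx))),
                           frame_idx)
    }
    # distances in original pixel space of the perturbed frame
    D2 <- colSums((flat - xf)^2)
    wts[idx] <- exp(-D2 / kernel_width^2)
  }
  if (all(Z == Z[rep(1, N), ]))
    warning("degenerate design: all perturbed samples identical")
  sdv <- stats::sd(scores)
  if (sdv < 1e-12) {
    # model insensitive to this frame: nothing to explain
    beta <- stats::setNames(numeric(d_prime), attr(mask, "labels")[labs])
    attr(beta, "intercept") <- mean(scores)
    attr(beta, "fidelity") <- NA_real_
    attr(beta, "loss") <- 0
    return(beta)
  }
  # the penalty acts on the normalised score scale, so explanations behave
  # identically whether the model's output varies by 0.5 or by 1e-3 (a
  # well-trained softmax saturates and perturbation effects become small)
  fit <- glmnet::glmnet(Z, scores, weights = wts, alpha = 1,
                        lambda = lasso_penalty * sdv, standardize = FALSE,
                        intercept = TRUE)
  beta <- as.numeric(fit$beta)
  a0 <- as.numeric(fit$a0)
  pred <- a0 + Z %*% beta
  wmean <- sum(wts * scores) / sum(wts)
  sse <- sum(wts * (scores - pred)^2)
  sst <- sum(wts * (scores - wmean)^2)
  names(beta) <- attr(mask, "labels")[labs]
  attr(beta, "intercept") <- a0
  attr(beta, "fidelity") <- if (sst > 0) 1 - sse / sst else NA_real_
  attr(beta, "loss") <- sse / sum(wts)
  beta
}

#' Explain a whole sequence frame by frame
#'
#' Applies [explain_frame()] to each of the T frames (LIME applied T times,
#' one frame perturbed at a time with the rest unchanged), giving a
#' `T x d'` coefficient map.
#'
#' @inheritParams explain_frame
#' @param frames frames to explain (default: all).
#' @return object of class `explanation_map`: matrix `T x d'` with dimnames
#'   (frame, electrode) and attributes `class`, `fidelity` (per frame),
#'   `loss` (per frame), `subject_id`.
#' @export
explain_sequence <- function(model, sequence, mask, N = 10000,
                             lasso_penalty = 1e-3, seed = 1,
                             class = "dyslexic", frames = NULL, ...) {
  T_ <- dim(sequence)[4]
  if (is.null(frames)) frames <- seq_len(T_)
  labs <- attr(mask, "labels")[sort(setdiff(unique(as.vector(unclass(mask))), 0L))]
  out <- matrix(0, length(frames), length(labs),
                dimnames = list(paste0("frame", frames), labs))
  fid <- loss <- numeric(length(frames))
  for (i in seq_along(frames)) {
    b <- explain_frame(model, sequence, frames[i], mask, N = N,
                       lasso_penalty = lasso_penalty,
                       seed = seed + frames[i], class = class, ...)
    out[i, ] <- b
    fid[i] <- attr(b, "fidelity")
    loss[i] <- attr(b, "loss")
  }
  structure(out, class = "explanation_map", explained_class = class,
            fidelity = fid, loss = loss,
            subject_id = attr(sequence, "subject_id"), frames = frames)
}

#' @export
print.explanation_map <- function(x, ...) {
  cat(sprintf("<explanation_map> %s: %d frames x %d super-pixels (class %s)\n",
              attr(x, "subject_id") %||% "?", nrow(x), ncol(x),
              attr(x, "explained_class")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate explanations: top super-pixels per frame
#'
#' Averages explanation maps over the selected subjects and ranks
#' super-pixels per frame by the magnitude of the average coefficient,
#' keeping the `k` most important; positive averages contribute toward the
#' explained class (rendered green), negative against it (red).
#'
#' @param maps list of `explanation_map`s (same shape).
#' @param correct optional logical vector: restrict averaging to correctly
#'   classified subjects.
#' @param k how many super-pixels per frame.
#' @return list of class `top_superpixels`: `average` (frames x d'),
#'   `ranking` (list per frame of the k electrode names, by |average|),
#'   `signed` (their signed average relevances).
#' @export
top_superpixels <- function(maps, correct = NULL, k = 5) {
  if (!is.null(correct)) {
    if (length(correct) != length(maps))
      stop("one correctness flag per subject required")
    maps <- maps[correct]
  }
  if (length(maps) == 0) stop("no subjects selected for aggregation")
  avg <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  k <- as.integer(min(k, ncol(avg)))
  ranking <- lapply(seq_len(nrow(avg)), function(t) {
    ord <- order(abs(avg[t, ]), decreasing = TRUE)[seq_len(k)]
    colnames(avg)[ord]
  })
  signed <- lapply(seq_len(nrow(avg)), function(t) {
    ord <- order(abs(avg[t, ]), decreasing = TRUE)[seq_len(k)]
    stats::setNames(avg[t, ord], colnames(avg)[ord])
  })
  structure(list(average = avg, ranking = ranking, signed = signed, k = k),
            class = "top_superpixels")
}

#' @export
print.top_superpixels <- function(x, ...) {
  cat(sprintf("<top_superpixels> top-%d per frame (%d frames)\n",
              x$k, nrow(x$average)))
  show <- utils::head(seq_len(nrow(x$average)), 5)
  for (t in show)
    cat(sprintf("  frame %2d: %s\n", t,
                paste(sprintf("%s(%+.3f)", names(x$signed[[t]]),
                              x$signed[[t]]), collapse = " ")))
  if (nrow(x$average) > 5) cat("  ...\n")
  invisible(x)
}

#' Render a relevance row as a signed super-pixel image
#'
#' Paints each super-pixel of the mask with its (signed) relevance; used for
#' the green/red top-super-pixel panels.
#'
#' @param relevance named numeric vector (electrode -> relevance) or one row
#'   of an aggregation `average`.
#' @param mask a [build_feature_mask()].
#' @param top_k keep only the `top_k` largest |relevance| (0 elsewhere);
#'   `Inf` keeps all.
#' @return `mesh x mesh` numeric matrix (positive = toward the class).
#' @export
render_relevance <- function(relevance, mask, top_k = Inf) {
  labs <- attr(mask, "labels")
  vals <- stats::setNames(numeric(length(labs)), labs)
  vals[names(relevance)] <- relevance
  if (is.finite(top_k) && top_k < length(vals)) {
    keep <- order(abs(vals), decreasing = TRUE)[seq_len(top_k)]
    vals[-keep] <- 0
  }
  m <- unclass(mask)
  img <- matrix(0, nrow(m), ncol(m))
  inh <- m > 0
  img[inh] <- vals[m[inh]]
  img
}

#' Write explanation maps as tidy CSV
#'
#' @param map an `explanation_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_explanation_csv <- function(map, path) {
  df <- expand.grid(frame = attr(map, "frames"),
                    electrode = colnames(map),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$coefficient <- as.vector(unclass(map))
  df$class <- attr(map, "explained_class")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
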