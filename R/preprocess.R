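#' Frame stack
#'
#' One band's trial recording: a `(frames x height x width)` array of camera
#' intensities with its acquisition metadata.  The frame count must equal
#' the protocol duration times the frame rate.
#'
#' @param data numeric array, dim `(n_frames, height, width)`.
#' @param band band label (e.g. `"GREEN"`).
#' @param protocol a [stim_protocol()].
#' @param corrected logical; `TRUE` for signed, illumination-corrected data.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(data, band = "BAND", protocol = stim_protocol(),
                        corrected = FALSE) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            inherits(protocol, "stim_protocol"))
  if (dim(data)[1] != n_frames(protocol))
    stop("frame_stack: ", dim(data)[1], " frames but protocol implies ",
         n_frames(protocol))
  if (!all(is.finite(data))) stop("frame_stack: intensities must be finite")
  structure(list(data = data, band = band, protocol = protocol,
                 frame_rate = protocol$frame_rate_hz,
                 corrected = isTRUE(corrected)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: band %s, %d frames of %d x %d px%s\n",
              x$band, d[1], d[2], d[3],
              if (x$corrected) " (illumination-corrected)" else ""))
  invisible(x)
}

# stack data as a (frames x pixels) matrix; pixels in column-major (row, col)
.as_tp <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, d[1], d[2] * d[3])
}

.from_tp <- function(M, like, corrected = like$corrected) {
  d <- dim(like$data)
  frame_stack(array(M, dim = d), band = like$band, protocol = like$protocol,
              corrected = corrected)
}

# normalized 1D Gaussian weights truncated at `truncate` sigma
.gauss_weights <- function(sigma, truncate = 4) {
  radius <- max(1L, as.integer(ceiling(truncate * sigma)))
  w <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  w / sum(w)
}

# n x n separable-convolution operator with symmetric (reflect) boundary
.conv_operator <- function(n, sigma, truncate = 4) {
  w <- .gauss_weights(sigma, truncate)
  radius <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (d in (-radius):radius) {
    j <- i + d
    # reflect about the half-sample edge: positions ..., 2, 1 | 1, 2, ...
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    K[cbind(i, j)] <- K[cbind(i, j)] + w[d + radius + 1L]
  }
  K
}

# 2D separable Gaussian convolution of a matrix, reflect boundary
conv2_sep <- function(M, sigma, truncate = 4) {
  K1 <- .conv_operator(nrow(M), sigma, truncate)
  K2 <- .conv_operator(ncol(M), sigma, truncate)
  K1 %*% M %*% t(K2)
}

#' Spatial Gaussian filtering of a frame stack
#'
#' Convolves every frame with a normalised 2D Gaussian kernel (separable,
#' truncated at 4 sigma, symmetric/reflected boundary).  The default width
#' of 2 px matches the preprocessing the package's analyses assume.
#'
#' @param stack a [frame_stack()].
#' @param sigma_px Gaussian width in pixels (`> 0`).
#' @return the filtered [frame_stack()].
#' @export
spatial_filter <- function(stack, sigma_px = 2) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!is.finite(sigma_px) || sigma_px <= 0)
    stop("spatial_filter: sigma_px must be > 0")
  d <- dim(stack$data)
  K1 <- .conv_operator(d[2], sigma_px)
  K2 <- .conv_operator(d[3], sigma_px)
  # convolve along rows for all (frame, col) at once, then along columns
  A <- aperm(stack$data, c(2, 1, 3))                 # h x T x w
  A <- array(K1 %*% matrix(A, d[2]), dim = c(d[2], d[1], d[3]))
  A <- aperm(A, c(3, 2, 1))                          # w x T x h
  A <- array(K2 %*% matrix(A, d[3]), dim = c(d[3], d[1], d[2]))
  .from_tp(matrix(aperm(A, c(2, 3, 1)), d[1]), stack)
}

#' Region-of-interest mask
#'
#' @param mask logical height-by-width matrix with at least one `TRUE` pixel.
#' @param role `"reference"` (illumination correction) or `"active"` (OIS
#'   region).
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, role = c("reference", "active")) {
  role <- match.arg(role)
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("roi_mask: mask has no TRUE pixel")
  structure(list(mask = mask, role = role), class = "roi_mask")
}

#' Default reference region: the image border frame
#'
#' The reference region used for illumination correction defaults to a
#' border band of the field of view (which shares the global illumination
#' but is far from the responsive tissue), minus any pixels of an excluded
#' candidate active region.
#'
#' @param height,width frame size, pixels.
#' @param margin border band width, pixels.
#' @param exclude optional logical matrix (or `roi_mask`) of pixels to drop.
#' @return an `roi_mask` with role `"reference"`.
#' @export
default_reference_mask <- function(height, width, margin = 10, exclude = NULL) {
  m <- matrix(FALSE, height, width)
  m[c(seq_len(margin), height - seq_len(margin) + 1L), ] <- TRUE
  m[, c(seq_len(margin), width - seq_len(margin) + 1L)] <- TRUE
  if (!is.null(exclude)) {
    e <- if (inherits(exclude, "roi_mask")) exclude$mask else exclude
    m <- m & !e
  }
  roi_mask(m, "reference")
}

#' Reference-region illumination correction
#'
#' Removes shared multiplicative illumination fluctuations.  The reference
#' time profile `I_ref(t)` is the mean over the reference-region pixels;
#' each pixel is corrected as
#' \deqn{I_{corr}(t) = I(t) - \alpha I_{ref}(t), \qquad
#'       \alpha = \langle I(t) / I_{ref}(t) \rangle_t}
#' with the per-pixel normalisation coefficient `alpha` averaged over the
#' chosen window (the whole trial by default).  A purely multiplicative
#' global fluctuation shared with the reference region is removed exactly.
#'
#' @param stack a raw [frame_stack()].
#' @param reference an `roi_mask` (role `"reference"`) or logical matrix.
#' @param alpha_window `"trial"` (default) to average `alpha` over all
#'   frames, or `"baseline"` to use only pre-stimulus frames.
#' @return a signed, corrected [frame_stack()] (counts).
#' @export
illumination_correct <- function(stack, reference,
                                 alpha_window = c("trial", "baseline")) {
  alpha_window <- match.arg(alpha_window)
  stopifnot(inherits(stack, "frame_stack"))
  m <- if (inherits(reference, "roi_mask")) reference$mask else reference
  if (!any(m)) stop("illumination_correct: empty reference mask")
  M <- .as_tp(stack)
  r <- rowMeans(M[, as.vector(m), drop = FALSE])
  if (any(r <= 0))
    stop("illumination_correct: non-positive reference intensity at some frame")
  if (any(r < 0.01 * stats::median(r)))
    stop("illumination_correct: reference intensity below 1% of its median")
  frames <- if (alpha_window == "baseline") {
    window_frames(stack$protocol, c(0, stack$protocol$baseline_s))
  } else {
    seq_along(r)
  }
  alpha <- colMeans(M[frames, , drop = FALSE] / r[frames])
  corr <- M - outer(r, alpha)
  .from_tp(corr, stack, corrected = TRUE)
}

#' Average a set of trials frame by frame
#'
#' @param trials a `trial_set` (from [render_trials()]) or a list of
#'   [frame_stack()] objects of identical shape.
#' @return the per-frame arithmetic mean as a [frame_stack()].
#' @export
average_trials <- function(trials) {
  lst <- if (inherits(trials, "trial_set")) trials$trials else trials
  stopifnot(is.list(lst), length(lst) >= 1L,
            all(vapply(lst, inherits, logical(1), "frame_stack")))
  d <- dim(lst[[1]]$data)
  for (s in lst)
    if (!identical(dim(s$data), d))
      stop("average_trials: trials have mismatched shapes")
  acc <- lst[[1]]$data
  if (length(lst) > 1L)
    for (k in 2:length(lst)) acc <- acc + lst[[k]]$data
  .from_tp(matrix(acc / length(lst), d[1]), lst[[1]])
}
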