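# Internal helpers shared across stages.

#' Derive a per-stage seed from the global seed
#'
#' All randomness in the pipeline flows from one global seed; each stage mixes
#' the stage name into it with a small deterministic hash so stages stay
#' independent but reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97) %% 2147483629)
}

# circular integer roll of a matrix by (dr, dc)
rollMatrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  if (dr %% nr != 0) m <- m[((seq_len(nr) - 1L - dr) %% nr) + 1L, , drop = FALSE]
  if (dc %% nc != 0) m <- m[, ((seq_len(nc) - 1L - dc) %% nc) + 1L, drop = FALSE]
  m
}

# translate by (dr, dc) with zero fill (content moves down/right for positive)
translateMatrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# binary disk mask of pixel radius r (inclusive Euclidean)
diskOffsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

# stamp value into matrix at disk around (row, col); returns modified matrix
stampDisk <- function(m, row, col, r, value, annulusInner = NULL) {
  off <- diskOffsets(r)
  if (!is.null(annulusInner))
    off <- off[off$dr^2 + off$dc^2 > annulusInner^2, , drop = FALSE]
  rr <- row + off$dr; cc <- col + off$dc
  ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  m[cbind(rr[ok], cc[ok])] <- value
  m
}

# Euclidean distance of every pixel to the nearest TRUE pixel of mask
distanceToMask <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  EBImage::distmap(1 - mask, metric = "euclidean")
}

assertImage <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
}

assertSameShape <- function(a, b) {
  if (!all(dim(a)[1:2] == dim(b)[1:2]))
    stop("image shape mismatch: ", paste(dim(a)[1:2], collapse = "x"),
         " vs ", paste(dim(b)[1:2], collapse = "x"), call. = FALSE)
}

# matrix -> EBImage Image and back; EBImage ops are axis-symmetric so we keep
# [row, col] matrices throughout and only wrap when an op requires Image
asImg <- function(m) EBImage::Image(m)
asMat <- function(i) {
  m <- EBImage::imageData(i)
  dim(m) <- dim(m)[1:2]
  m
}

# Otsu threshold on a numeric vector via a 256-bin histogram over [lo, hi]
otsuThreshold <- function(x, nbins = 256L, lo = 0, hi = 1) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) return(NA_real_)
  br <- seq(lo, hi, length.out = nbins + 1L)
  x <- pmin(pmax(x, lo), hi)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); mu <- cumsum(h * mids)
  wT <- w[nbins]; muT <- mu[nbins]
  w0 <- w[-nbins]; w1 <- wT - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (muT * w0[valid] - wT * mu[-nbins][valid])^2 /
    (w0[valid] * w1[valid])
  if (!any(is.finite(between))) return(NA_real_)
  mx <- max(between)
  ties <- which(between >= mx - abs(mx) * 1e-12)  # argmax plateau across the gap
  k <- ties[ceiling(length(ties) / 2)]            # mid-plateau convention
  mids[k] + (mids[2] - mids[1]) / 2
}
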