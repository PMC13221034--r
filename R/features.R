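# Simple fixed feature extractors used to verify that the synthetic
# families carry category signal: mean-color plus orientation-energy
# features for textures, and moment/compactness features for shape
# silhouettes, with a nearest-centroid classifier on top.

#' Texture features: mean color, chroma direction and orientation energy
#'
#' Mean per-channel color, the circular direction of the mean chroma
#' (hue, as cosine/sine so it wraps), per-channel contrast, and the
#' energies of horizontal, vertical and the two diagonal
#' finite-difference derivatives of the luminance image, log-scaled and
#' normalized to their total so they express orientation rather than
#' overall contrast.
#'
#' @param tex a texture object (or H x W x 3 array).
#' @return named numeric feature vector.
#' @export
texture_features <- function(tex) {
  px <- if (is.list(tex)) tex$pixels else tex
  lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  dh <- lum[, -1] - lum[, -ncol(lum)]
  dv <- lum[-1, ] - lum[-nrow(lum), ]
  dd1 <- lum[-1, -1] - lum[-nrow(lum), -ncol(lum)]
  dd2 <- lum[-1, -ncol(lum)] - lum[-nrow(lum), -1]
  e <- c(mean(dh^2), mean(dv^2), mean(dd1^2), mean(dd2^2))
  eo <- e / (sum(e) + 1e-12)
  mu <- apply(px, 3, mean)
  # hue angle of the mean color relative to its gray point
  op1 <- mu[1] - mu[2]                     # red-green opponent axis
  op2 <- (mu[1] + mu[2]) / 2 - mu[3]       # yellow-blue opponent axis
  ang <- atan2(op2, op1)
  c(mean_r = mu[1], mean_g = mu[2], mean_b = mu[3],
    hue_cos = cos(ang), hue_sin = sin(ang),
    sd_r = stats::sd(px[, , 1]), sd_g = stats::sd(px[, , 2]),
    sd_b = stats::sd(px[, , 3]),
    o_h = eo[1], o_v = eo[2], o_d1 = eo[3], o_d2 = eo[4],
    e_tot = log1p(sum(e) * 1e3))
}

#' Silhouette shape features
#'
#' Scale-invariant descriptors of a binary mask: fill fraction of the
#' bounding box, aspect ratio, perimeter-squared-over-area compactness,
#' normalized second-order central moments, eccentricity, and coarse
#' radial-profile statistics of the boundary.
#'
#' @param mask logical or 0/1 matrix.
#' @return named numeric feature vector (zeros for an empty mask).
#' @export
silhouette_features <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  a <- sum(m)
  if (a == 0) return(stats::setNames(numeric(9),
    c("extent", "aspect", "compact", "nu20", "nu02", "nu11", "ecc",
      "rad_cv", "vskew")))
  ys <- row(m)[m > 0]; xs <- col(m)[m > 0]
  h <- diff(range(ys)) + 1; w <- diff(range(xs)) + 1
  # boundary: figure pixels with at least one background 4-neighbor
  pad <- rbind(0, cbind(0, m, 0), 0)
  nb <- pad[1:nrow(m), 2:(ncol(m) + 1)] + pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)] +
        pad[2:(nrow(m) + 1), 1:ncol(m)] + pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
  bound <- m > 0 & nb < 4
  per <- sum(bound)
  cy <- mean(ys); cx <- mean(xs)
  mu20 <- mean((xs - cx)^2); mu02 <- mean((ys - cy)^2); mu11 <- mean((xs - cx) * (ys - cy))
  tr <- mu20 + mu02
  disc <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  rb <- sqrt((row(m)[bound] - cy)^2 + (col(m)[bound] - cx)^2)
  c(extent = a / (h * w), aspect = w / h, compact = per^2 / a,
    nu20 = mu20 / a, nu02 = mu02 / a, nu11 = mu11 / a,
    ecc = if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0,
    rad_cv = stats::sd(rb) / mean(rb),
    vskew = mean(((ys - cy) / sqrt(mu02 + 1e-9))^3))
}

#' Nearest-centroid classification
#'
#' Trains per-class centroids on z-scaled features and classifies test
#' rows by Euclidean distance, the fixed simple classifier used to check
#' that texture and shape categories are separable by construction.
#'
#' @param train_x,train_y training feature matrix and labels.
#' @param test_x test feature matrix.
#' @return character vector of predicted labels.
#' @export
nearest_centroid <- function(train_x, train_y, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, stats::sd)
  sdv[sdv < 1e-9] <- 1
  zs <- function(X) sweep(sweep(X, 2, mu), 2, sdv, `/`)
  tr <- zs(train_x); te <- zs(test_x)
  cents <- rowsum(tr, train_y) / as.vector(table(train_y)[sort(unique(train_y))])
  d <- outer(rowSums(te^2), rep(1, nrow(cents))) - 2 * te %*% t(cents) +
    outer(rep(1, nrow(te)), rowSums(cents^2))
  rownames(cents)[max.col(-d, ties.method = "first")]
}
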