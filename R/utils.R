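# small shared helpers -------------------------------------------------------

vnorm <- function(x) sqrt(sum(x * x))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

#' Derive a per-stage random seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own substream seed from the
#' global seed so that stages can be rerun independently yet reproducibly.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483587L) + 1L
}

# 3x3 rotation about a unit axis by angle (radians), Rodrigues
rotation_matrix <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# symmetric tensor <-> 6-vector (xx, yy, zz, xy, xz, yz)
tensor6_to_mat <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

mat_to_tensor6 <- function(M) {
  c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
}

# FA from eigenvalues (vectorized over columns of a 3 x n matrix)
fa_from_eigenvalues <- function(lambda) {
  if (is.null(dim(lambda))) lambda <- matrix(lambda, nrow = 3)
  mb <- colMeans(lambda)
  num <- (lambda[1, ] - mb)^2 + (lambda[2, ] - mb)^2 + (lambda[3, ] - mb)^2
  den <- lambda[1, ]^2 + lambda[2, ]^2 + lambda[3, ]^2
  fa <- sqrt(1.5) * sqrt(num / den)
  fa[den == 0] <- 0
  fa
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# fold an angle in degrees to (-90, 90]
fold90 <- function(a) {
  a <- (a + 90) %% 180
  a[a == 0] <- 180
  a - 90
}

# circular mean of axial angles (degrees, (-90,90]) via doubled-angle embedding
axial_mean_deg <- function(a) {
  t2 <- rad(2 * a)
  fold90(deg(atan2(mean(sin(t2)), mean(cos(t2)))) / 2)
}
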