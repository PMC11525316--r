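# geometric fixtures shared across test files

# vertices of a regular n-gon of circumradius r, optionally rotated
regular_polygon <- function(n, r = 1, rot = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n + rot
  cbind(r * cos(th), r * sin(th))
}

# closed-form circularity of a regular n-gon
ngon_C <- function(n) (pi / n) / tan(pi / n)

# matrix of pairwise circular angular distances between tone degrees
circ_dist_matrix <- function(degrees) {
  d <- abs(outer(degrees, degrees, "-")) %% 360
  d <- pmin(d, 360 - d)
  dimnames(d) <- list(degrees, degrees)
  d
}

# a perceptual_config sitting exactly on a circle, labeled by degree
circle_config <- function(degrees, r = 1) {
  th <- degrees * pi / 180
  structure(list(labels = degrees, points = cbind(r * cos(th), r * sin(th)),
                 stress = 0),
            class = "perceptual_config")
}

# symmetric Procrustes residual after optimal rotation/reflection/scale
procrustes_residual <- function(X, Y) {
  cx <- scale(X, scale = FALSE); cy <- scale(Y, scale = FALSE)
  s <- svd(crossprod(cx, cy))        # t(cx) %*% cy
  R <- s$u %*% t(s$v)                # optimal map cx -> cy
  sc <- sum(s$d) / sum(cx^2)
  sqrt(mean((cy - sc * cx %*% R)^2))
}
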