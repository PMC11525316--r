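make_rating_rows <- function(id, a, b, r) {
  data.frame(participant_id = id, tone_a = a, tone_b = b, rating = r,
             stringsAsFactors = FALSE)
}

test_that("self-similarity exclusion retains only discriminating participants", {
  tr <- rbind(
    make_rating_rows("good", c(10, 10, 20, 20, 10), c(10, 10, 20, 20, 20),
                     c(5, 4, 4, 5, 3)),                     # self mean 4.5
    make_rating_rows("bad", c(10, 20, 10), c(10, 20, 20), c(3, 4, 2)))  # 3.5
  expect_equal(exclude_participants(tr), "good")
  tr2 <- rbind(tr, make_rating_rows("noself", 10, 20, 4))
  expect_error(exclude_participants(tr2), "noself")
})

test_that("similarity aggregation is order-blind and symmetric", {
  tr <- make_rating_rows("p", c(10, 20, 10, 20), c(20, 10, 10, 20),
                         c(4, 2, 5, 5))
  m <- aggregate_similarity(tr, "p")
  expect_equal(m["10", "20"], 3)       # mean of 4 and 2, both orders pooled
  expect_equal(m["20", "10"], 3)
  expect_equal(m["10", "10"], 5)
  # a missing pair is named in the error
  tr3 <- make_rating_rows("p", c(1, 2, 3), c(1, 2, 3), c(5, 5, 5))
  expect_error(aggregate_similarity(tr3, "p"), "pair")
})

test_that("a full 9-tone design aggregates to a complete 9x9 matrix", {
  ratings <- gen_similarity_study(n_per_set = 1, n_low_self = 0, seed = 3)
  p1 <- unique(ratings$participant_id)[1]
  m <- aggregate_similarity(ratings, p1)
  expect_equal(dim(m), c(9, 9))
  expect_true(isSymmetric(unname(m)))
  expect_true(all(diag(m) >= 4))
})

test_that("group dissimilarity reverse-codes the 0-5 scale linearly", {
  labs <- c("10", "20")
  mk <- function(v) matrix(v, 2, 2, dimnames = list(labs, labs))
  expect_equal(group_dissimilarity(list(mk(5))), mk(0))
  expect_equal(group_dissimilarity(list(mk(3.98)))[1, 2], 1.02)
  # averaging participants then reverse-coding == cell-wise average
  m1 <- mk(c(5, 4, 4, 5)); m2 <- mk(c(3, 2, 2, 3))
  expect_equal(group_dissimilarity(list(m1, m2)), 5 - (m1 + m2) / 2)
  bad <- matrix(1, 2, 2, dimnames = list(c("10", "99"), c("10", "99")))
  expect_error(group_dissimilarity(list(m1, bad)), "labels")
})

test_that("metric MDS recovers exactly embeddable configurations", {
  set.seed(7)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(1:10, 1:10)
  cfg <- mds_embed(D)
  expect_lt(procrustes_residual(X, cfg$points), 1e-6)
  expect_lt(cfg$stress, 1e-6)

  # duplicated point (zero dissimilarity) embeds coincident
  X2 <- rbind(X, X[1, ])
  D2 <- as.matrix(dist(X2)); dimnames(D2) <- list(1:11, 1:11)
  cfg2 <- mds_embed(D2)
  expect_lt(sqrt(sum((cfg2$points[11, ] - cfg2$points[1, ])^2)), 1e-6)

  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|4")
})

test_that("circular-distance dissimilarities embed on a near-perfect circle", {
  D <- circ_dist_matrix(seq(24, 360, by = 24))
  cfg <- mds_embed(D)
  curve <- periodic_spline(cfg)
  expect_gte(curve$C, 0.95)
  # embedded label order around the centroid is a cyclic (possibly
  # reflected) copy of the true tone order
  ctr <- colMeans(cfg$points)
  ang <- atan2(cfg$points[, 2] - ctr[2], cfg$points[, 1] - ctr[1])
  walked <- cfg$labels[order(ang)]
  is_rotation_of <- function(x, y) {
    n <- length(y)
    any(vapply(seq_len(n), function(s)
      identical(x, y[((seq_len(n) + s - 2) %% n) + 1]), logical(1)))
  }
  truth <- sort(cfg$labels)
  expect_true(is_rotation_of(walked, truth) ||
              is_rotation_of(rev(walked), truth))
})

test_that("affine alignment matches anchors exactly and admits reflections", {
  deg <- seq(40, 360, by = 40)
  ref <- circle_config(deg)
  rot <- pi / 2
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  src <- ref
  src$points <- 2 * ref$points %*% R + 0.3
  out <- affine_align(src, ref, anchor_labels = c(40, 160, 280))
  expect_equal(out$points, ref$points, tolerance = 1e-9)

  refl <- ref; refl$points <- ref$points %*% diag(c(-1, 1))
  out2 <- affine_align(refl, ref, anchor_labels = c(40, 160, 280))
  expect_equal(out2$points, ref$points, tolerance = 1e-9)

  line_cfg <- structure(list(labels = 1:4,
                             points = cbind(1:4, 2 * (1:4)), stress = 0),
                        class = "perceptual_config")
  expect_error(affine_align(line_cfg, line_cfg, anchor_labels = 1:3),
               "collinear")
})

test_that("combining aligned sets merges anchors and keeps other labels", {
  s1 <- c(48, 96, 120, 168, 216, 240, 288, 336, 360)
  s2 <- c(24, 72, 120, 144, 192, 240, 264, 312, 360)
  anchors <- c(120, 240, 360)
  c1 <- circle_config(s1)
  c2 <- circle_config(s2)
  comb <- combine_configurations(c1, c2, anchors)
  expect_equal(length(comb$labels), 15)
  expect_equal(comb$labels, sort(union(s1, s2)))

  # identical configurations combine to themselves
  same <- combine_configurations(c1, c1, s1)
  expect_equal(same$points, c1$points[order(c1$labels), ])

  # symmetric anchor offsets average to the midpoint
  c2b <- c2
  i <- match(120, c2$labels)
  c2b$points[i, ] <- c2$points[i, ] + c(0.2, 0)
  c1b <- c1
  j <- match(120, c1$labels)
  c1b$points[j, ] <- c2$points[i, ] - c(0.2, 0)
  comb2 <- combine_configurations(c1b, c2b, anchors)
  expect_equal(comb2$points[match(120, comb2$labels), ], c2$points[i, ],
               tolerance = 1e-12)

  c_bad <- c2; c_bad$labels[1] <- 48   # collides with a non-anchor of set 1
  expect_error(combine_configurations(c1, c_bad, anchors), "collide")
})

test_that("the periodic spline closes, interpolates, and respects circles", {
  deg <- seq(30, 360, by = 30)
  cfg <- circle_config(deg, r = 2)
  curve <- periodic_spline(cfg)
  n <- nrow(curve$samples)
  expect_equal(curve$samples[1, ], curve$samples[n, ], tolerance = 1e-9)
  r <- sqrt(rowSums(curve$samples^2))
  expect_lt(diff(range(r)) / 2, 1e-3 * 2)      # radius constant to 1e-3 rel.
  # passes through every input point (grid chosen to land on the knots)
  aligned <- periodic_spline(cfg, samples = 1200)$samples
  for (k in seq_along(deg)) {
    d <- min(sqrt(rowSums((aligned -
                           matrix(cfg$points[k, ], nrow(aligned), 2,
                                  byrow = TRUE))^2)))
    expect_lt(d, 1e-9)
  }
  # a square's corners still produce a closed smooth loop through all corners
  sq <- structure(list(labels = c(90, 180, 270, 360),
                       points = regular_polygon(4), stress = 0),
                  class = "perceptual_config")
  sq_curve <- periodic_spline(sq)
  expect_s3_class(sq_curve, "closed_curve")
  expect_gt(sq_curve$C, circularity(regular_polygon(4)))

  # doubling the sampling changes C by less than 1e-4
  expect_lt(abs(periodic_spline(cfg, 2000)$C - curve$C), 1e-4)

  dup <- cfg; dup$labels[2] <- dup$labels[1]
  expect_error(periodic_spline(dup), "duplicate")
})

test_that("spline closure never hurts near-circular polygons", {
  for (n in seq(8, 20, by = 3)) {
    deg <- seq(360 / n, 360, by = 360 / n)
    cfg <- circle_config(deg)
    expect_gte(periodic_spline(cfg)$C, circularity(cfg$points) - 1e-12)
  }
})

test_that("circularity matches closed forms and is invariant to similarity maps", {
  expect_equal(circularity(regular_polygon(4)), pi / 4, tolerance = 1e-12)
  for (n in c(3, 7, 16, 30))
    expect_equal(circularity(regular_polygon(n)), ngon_C(n), tolerance = 1e-9)

  set.seed(11)
  pts <- regular_polygon(9, r = 3)
  C0 <- circularity(pts)
  rot <- 0.7
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  expect_equal(circularity(pts %*% R), C0, tolerance = 1e-9)
  expect_equal(circularity(pts %*% diag(c(-1, 1))), C0, tolerance = 1e-9)
  expect_equal(circularity(pts * 17 + 5), C0, tolerance = 1e-9)

  expect_warning(circularity(cbind(c(0, 4, 1, 3), c(0, 0, 2, 2))),
                 "self-intersecting")
  expect_error(circularity(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("isoperimetric bound holds for random smooth closed shapes", {
  set.seed(5)
  for (rep in 1:20) {
    th <- seq(0, 2 * pi, length.out = 400)
    r <- 1 + 0.25 * (sin(3 * th + runif(1, 0, 2 * pi)) * runif(1) +
                     cos(5 * th) * runif(1, 0, 0.5))
    expect_lte(circularity(cbind(r * cos(th), r * sin(th))), 1 + 1e-6)
  }
  # dense regular polygon approaches the circle bound from below
  expect_lte(circularity(regular_polygon(2000)), 1)
})

test_that("radial noise degrades expected circularity monotonically", {
  mean_C <- function(noise_sd) {
    mean(vapply(1:25, function(i) {
      set.seed(1000 + i)
      th <- seq(0, 2 * pi, length.out = 16)[-16]
      r <- 1 + rnorm(15, 0, noise_sd)
      circularity(cbind(r * cos(th), r * sin(th)))
    }, numeric(1)))
  }
  cs <- vapply(c(0, 0.05, 0.15), mean_C, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("end-to-end pipeline: clean ratings circle, null ratings collapse", {
  clean <- gen_similarity_study(noise_sd = 0, n_low_self = 0,
                                discretize = FALSE, seed = 5)
  rep_clean <- suppressWarnings(circularity_report(clean))
  expect_gte(rep_clean$C_spline, 0.9)
  expect_equal(rep_clean$n_retained, 28)

  null <- gen_similarity_study(b = 0, n_low_self = 0, seed = 5)
  rep_null <- suppressWarnings(circularity_report(null))
  expect_lt(rep_null$C_spline, 0.7)
  expect_gt(max(rep_null$stress), max(rep_clean$stress))
})

test_that("single-participant analysis path works without alignment", {
  ratings <- gen_similarity_study(n_per_set = 1, n_low_self = 0,
                                  noise_sd = 0.3, seed = 9)
  one <- ratings[ratings$set == 1, ]
  rep1 <- suppressWarnings(circularity_report(one))
  expect_equal(rep1$n_retained, 1)
  expect_equal(length(rep1$configuration$labels), 9)
  expect_true(is.finite(rep1$C_spline))
})
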