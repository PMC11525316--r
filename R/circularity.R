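#' Apply the self-similarity exclusion rule to a similarity-rating table
#'
#' Participants who do not rate identical tone pairs as highly similar cannot
#' discriminate the tones well enough for their data to be usable: a
#' participant is retained only if their mean rating on identical-pair trials
#' (tone_a == tone_b) is at least \code{threshold} on the 0--5 Likert scale.
#'
#' @param trials Data frame with columns \code{participant_id},
#'   \code{tone_a}, \code{tone_b}, \code{rating}.
#' @param threshold Minimum mean self-similarity rating (default 4).
#' @return Character vector of retained participant ids.
#' @export
exclude_participants <- function(trials, threshold = 4) {
  check_rating_trials(trials)
  ids <- unique(as.character(trials$participant_id))
  self <- trials[trials$tone_a == trials$tone_b, , drop = FALSE]
  missing <- setdiff(ids, unique(as.character(self$participant_id)))
  if (length(missing))
    stop("participant(s) without identical-pair trials: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- tapply(self$rating, as.character(self$participant_id), mean)
  ids[ids %in% names(m)[m >= threshold]]
}

#' Build a participant's symmetric similarity matrix
#'
#' Ratings of each unordered tone pair are averaged regardless of
#' presentation order; the diagonal holds the mean self-similarity ratings.
#'
#' @inheritParams exclude_participants
#' @param participant Participant id whose trials to aggregate.
#' @return Symmetric numeric matrix with tone degrees as dimnames.
#' @export
aggregate_similarity <- function(trials, participant) {
  check_rating_trials(trials)
  tr <- trials[as.character(trials$participant_id) == as.character(participant), ,
               drop = FALSE]
  if (!nrow(tr)) stop("no trials for participant ", participant, call. = FALSE)
  labels <- sort(unique(c(tr$tone_a, tr$tone_b)))
  n <- length(labels)
  sums <- counts <- matrix(0, n, n, dimnames = list(labels, labels))
  ia <- match(tr$tone_a, labels); ib <- match(tr$tone_b, labels)
  for (k in seq_len(nrow(tr))) {
    i <- ia[k]; j <- ib[k]
    sums[i, j] <- sums[i, j] + tr$rating[k]; counts[i, j] <- counts[i, j] + 1
    if (i != j) { sums[j, i] <- sums[j, i] + tr$rating[k]
                  counts[j, i] <- counts[j, i] + 1 }
  }
  if (any(counts == 0)) {
    miss <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("no rating observed for pair (%s, %s)",
                 labels[miss[1]], labels[miss[2]]), call. = FALSE)
  }
  sums / counts
}

#' Group-level dissimilarity matrix from participant similarity matrices
#'
#' Averages the participants' similarity matrices cell-wise and reverse-codes
#' on the 0--5 scale: dissimilarity = 5 - mean similarity.
#'
#' @param matrices List of similarity matrices sharing dimnames.
#' @param scale_max Top of the Likert scale (default 5).
#' @return Symmetric dissimilarity matrix.
#' @export
group_dissimilarity <- function(matrices, scale_max = 5) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  labs <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), labs) || !identical(colnames(m), labs))
      stop("similarity matrices have mismatched labels", call. = FALSE)
  scale_max - Reduce(`+`, matrices) / length(matrices)
}

#' Embed a dissimilarity matrix in the plane with metric MDS
#'
#' Metric multidimensional scaling by stress majorization (SMACOF): the
#' configuration is initialized with classical scaling
#' (\code{\link[stats]{cmdscale}}) and improved by repeated Guttman
#' transforms until the raw stress decreases by less than \code{tol}
#' relative, or \code{max_iter} iterations. The reported \code{stress} is
#' stress-1, \eqn{\sqrt{\sum (\delta_{ij} - d_{ij})^2 / \sum d_{ij}^2}}.
#'
#' @param dissim Symmetric dissimilarity matrix with labels as dimnames.
#' @param dims Embedding dimension (default 2).
#' @param max_iter Iteration cap (default 300).
#' @param tol Relative stress-decrease tolerance (default 1e-9).
#' @return An object of class \code{perceptual_config}: list with
#'   \code{labels} (numeric tone degrees), \code{points} (n x dims matrix)
#'   and \code{stress}.
#' @export
mds_embed <- function(dissim, dims = 2, max_iter = 300, tol = 1e-9) {
  delta <- as.matrix(dissim)
  n <- nrow(delta)
  if (n < 4) stop("need at least 4 objects to embed", call. = FALSE)
  if (!isSymmetric(unname(delta), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  delta <- (delta + t(delta)) / 2
  diag(delta) <- 0
  X <- suppressWarnings(stats::cmdscale(delta, k = dims))
  if (ncol(X) < dims)
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  D <- as.matrix(stats::dist(X))
  sigma <- sum((delta - D)^2) / 2
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(D > 0, delta / D, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n                       # Guttman transform, unit weights
    D <- as.matrix(stats::dist(X))
    sigma_new <- sum((delta - D)^2) / 2
    if (sigma - sigma_new < tol * max(sigma, .Machine$double.eps)) {
      sigma <- sigma_new; break
    }
    sigma <- sigma_new
  }
  labs <- rownames(delta)
  structure(
    list(labels = if (is.null(labs)) seq_len(n) else as.numeric(labs),
         points = unname(X),
         stress = sqrt(sum((delta - D)^2) / sum(D^2))),
    class = "perceptual_config")
}

#' @export
print.perceptual_config <- function(x, ...) {
  cat(sprintf("Perceptual configuration: %d points in %d-D (stress-1 = %.4g)\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' Affine alignment of one configuration onto another via anchor tones
#'
#' Fits the 6-parameter 2-D affine map (rotation, scale, shear, translation,
#' reflection allowed) that carries the source anchors onto the reference
#' anchors in least squares, and applies it to every source point. With
#' exactly three non-collinear anchors the map interpolates them exactly.
#'
#' @param source,reference \code{perceptual_config} objects.
#' @param anchor_labels Tone degrees present in both configurations.
#' @return The source configuration with transformed points.
#' @export
affine_align <- function(source, reference, anchor_labels) {
  is_cfg <- function(x) inherits(x, "perceptual_config")
  stopifnot(is_cfg(source), is_cfg(reference))
  if (length(anchor_labels) < 3)
    stop("need at least 3 anchors", call. = FALSE)
  si <- match(anchor_labels, source$labels)
  ri <- match(anchor_labels, reference$labels)
  if (anyNA(si) || anyNA(ri))
    stop("anchor labels missing from a configuration", call. = FALSE)
  A <- cbind(source$points[si, , drop = FALSE], 1)
  if (qr(A)$rank < 3)
    stop("anchors are collinear; affine map is not identifiable", call. = FALSE)
  beta <- qr.solve(A, reference$points[ri, , drop = FALSE])
  out <- source
  out$points <- cbind(source$points, 1) %*% beta
  out
}

#' Merge two anchor-aligned configurations into one labeled point set
#'
#' Anchor tones (present in both) are replaced by the midpoint of their two
#' copies; all other labels must be disjoint. Output labels are sorted by
#' tone degree.
#'
#' @param cfg1 Reference \code{perceptual_config}.
#' @param cfg2_aligned Second configuration, already aligned to \code{cfg1}.
#' @param anchor_labels Shared tone degrees.
#' @return Combined \code{perceptual_config} (stress is \code{NA}).
#' @export
combine_configurations <- function(cfg1, cfg2_aligned, anchor_labels) {
  l1 <- cfg1$labels; l2 <- cfg2_aligned$labels
  shared <- intersect(l1, l2)
  if (!setequal(shared, anchor_labels))
    stop("non-anchor labels collide between configurations", call. = FALSE)
  labs <- sort(union(l1, l2))
  pts <- matrix(NA_real_, length(labs), 2)
  for (k in seq_along(labs)) {
    p1 <- cfg1$points[match(labs[k], l1), ]
    p2 <- cfg2_aligned$points[match(labs[k], l2), ]
    pts[k, ] <- if (labs[k] %in% anchor_labels) (p1 + p2) / 2
                else if (!anyNA(p1)) p1 else p2
  }
  structure(list(labels = labs, points = pts, stress = NA_real_),
            class = "perceptual_config")
}

#' Close a configuration with a periodic cubic spline
#'
#' The points, ordered by tone degree, are interpolated coordinate-wise by a
#' periodic cubic spline in the degree parameter and sampled densely; the
#' sampled loop passes through every input point and returns to its start.
#'
#' @param config \code{perceptual_config} with at least 4 points.
#' @param samples Number of curve samples (default 1000).
#' @return An object of class \code{closed_curve}: list with \code{samples}
#'   (closed (samples+1) x 2 matrix), \code{area}, \code{perimeter} and
#'   \code{C}.
#' @export
periodic_spline <- function(config, samples = 1000) {
  stopifnot(inherits(config, "perceptual_config"))
  if (anyDuplicated(config$labels))
    stop("duplicate tone degrees; ordering around the circle is ambiguous",
         call. = FALSE)
  ord <- order(config$labels)
  th <- config$labels[ord]
  if (length(th) < 4) stop("need at least 4 points", call. = FALSE)
  pts <- config$points[ord, , drop = FALSE]
  thc <- c(th, th[1] + 360)
  grid <- seq(thc[1], thc[length(thc)], length.out = samples + 1)
  xy <- vapply(1:2, function(j) {
    stats::spline(thc, c(pts[, j], pts[1, j]), xout = grid,
                  method = "periodic")$y
  }, numeric(length(grid)))
  curve_metrics(xy)
}

#' @export
print.closed_curve <- function(x, ...) {
  cat(sprintf("Closed curve: %d samples, area %.4g, perimeter %.4g, C = %.4f\n",
              nrow(x$samples) - 1, x$area, x$perimeter, x$C))
  invisible(x)
}

# area / perimeter / C of a closed sampled path (first row == last row)
curve_metrics <- function(xy) {
  n <- nrow(xy) - 1
  x <- xy[, 1]; y <- xy[, 2]
  signed_area <- sum(x[1:n] * y[2:(n + 1)] - x[2:(n + 1)] * y[1:n]) / 2
  perim <- sum(sqrt(diff(x)^2 + diff(y)^2))
  area <- abs(signed_area)
  if (area <= .Machine$double.eps * perim^2)
    stop("degenerate shape with zero area", call. = FALSE)
  structure(list(samples = xy, area = area, perimeter = perim,
                 C = 4 * pi * area / perim^2),
            class = "closed_curve")
}

#' Circularity quotient of a closed shape
#'
#' \eqn{C = 4\pi \, Area / Perimeter^2}: 1 for a perfect circle,
#' \eqn{(\pi/n)\cot(\pi/n)} for a regular n-gon (0.987 for a hexadecagon),
#' and strictly below 1 for every other shape (isoperimetric inequality).
#' Invariant to rotation, translation, reflection and uniform scaling. Area
#' is computed with the shoelace formula on the closed path; for
#' self-intersecting paths (detected for small polygons) the absolute signed
#' area is used with a warning.
#'
#' @param shape A \code{closed_curve}, or a matrix / data frame of polygon
#'   vertices in order (closed or open; an open polygon is closed
#'   automatically).
#' @return The circularity value \code{C}.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' circularity(sq)          # pi/4
#' @export
circularity <- function(shape) {
  if (inherits(shape, "closed_curve")) return(shape$C)
  xy <- as.matrix(shape)
  if (nrow(xy) < 3 || ncol(xy) != 2)
    stop("need at least 3 points in 2-D", call. = FALSE)
  if (any(abs(xy[1, ] - xy[nrow(xy), ]) > 1e-12 * (1 + max(abs(xy)))))
    xy <- rbind(xy, xy[1, ])
  if (nrow(xy) <= 101 && polygon_self_intersects(xy))
    warning("self-intersecting path; using absolute signed area")
  curve_metrics(xy)$C
}

# brute-force segment intersection test for small closed polygons
polygon_self_intersects <- function(xy) {
  n <- nrow(xy) - 1
  seg <- function(i) list(p = xy[i, ], q = xy[i + 1, ])
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2)) {
    for (j in seq.int(i + 2, n)) {
      if (i == 1 && j == n) next            # closing edge shares a vertex
      s1 <- seg(i); s2 <- seg(j)
      d1 <- cross2(s2$p, s2$q, s1$p); d2 <- cross2(s2$p, s2$q, s1$q)
      d3 <- cross2(s1$p, s1$q, s2$p); d4 <- cross2(s1$p, s1$q, s2$q)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' End-to-end circularity analysis of a similarity-rating study
#'
#' Runs the full pipeline on a trial-level rating table: participant
#' exclusion, per-participant similarity aggregation, per-set group
#' dissimilarity (reverse coding), metric MDS per participant set, affine
#' alignment of the second set onto the first via the anchors, combination,
#' periodic spline closure, and the circularity quotient. Participant sets
#' are identified by the distinct tone sets participants rated; a
#' single-set table (including a single participant) skips alignment.
#'
#' @inheritParams exclude_participants
#' @param anchors Tone degrees shared between participant sets (ignored for
#'   a single set).
#' @param spline_samples Samples for the closed spline (default 1000).
#' @return Object of class \code{circularity_report}: \code{C_spline},
#'   \code{C_polygon}, \code{configuration}, \code{curve}, \code{stress}
#'   (per set), \code{n_retained}, \code{excluded_ids}.
#' @export
circularity_report <- function(trials, anchors = c(120, 240, 360),
                               spline_samples = 1000) {
  check_rating_trials(trials)
  retained <- exclude_participants(trials)
  all_ids <- unique(as.character(trials$participant_id))
  trials <- trials[as.character(trials$participant_id) %in% retained, ,
                   drop = FALSE]
  if (!nrow(trials)) stop("no participants retained", call. = FALSE)

  sims <- lapply(retained, function(p) aggregate_similarity(trials, p))
  keys <- vapply(sims, function(m) paste(rownames(m), collapse = ","),
                 character(1))
  sets <- split(sims, factor(keys, levels = unique(keys)))
  if (length(sets) > 2)
    stop("more than two distinct tone sets found", call. = FALSE)

  cfgs <- lapply(sets, function(ms) mds_embed(group_dissimilarity(ms)))
  stress <- vapply(cfgs, `[[`, numeric(1), "stress")
  cfg <- if (length(cfgs) == 1) {
    cfgs[[1]]
  } else {
    aligned <- affine_align(cfgs[[2]], cfgs[[1]], anchors)
    combine_configurations(cfgs[[1]], aligned, anchors)
  }

  curve <- periodic_spline(cfg, samples = spline_samples)
  ord <- order(cfg$labels)
  poly_C <- circularity(cfg$points[ord, , drop = FALSE])
  structure(
    list(C_spline = curve$C, C_polygon = poly_C,
         configuration = cfg, curve = curve, stress = unname(stress),
         n_retained = length(retained),
         excluded_ids = setdiff(all_ids, retained)),
    class = "circularity_report")
}

#' @export
print.circularity_report <- function(x, ...) {
  cat("Circularity analysis of a similarity-rating study\n")
  cat(sprintf("  participants retained : %d (excluded: %s)\n", x$n_retained,
              if (length(x$excluded_ids)) paste(x$excluded_ids, collapse = ", ")
              else "none"))
  cat(sprintf("  MDS stress-1 per set  : %s\n",
              paste(sprintf("%.4f", x$stress), collapse = ", ")))
  cat(sprintf("  circularity C         : %.3f (splined), %.3f (polygon)\n",
              x$C_spline, x$C_polygon))
  invisible(x)
}

#' @param x A \code{circularity_report}.
#' @param ... Passed to \code{plot.default}.
#' @rdname circularity_report
#' @export
plot.circularity_report <- function(x, ...) {
  xy <- x$curve$samples
  plot(xy, type = "l", asp = 1, xlab = "dimension 1", ylab = "dimension 2",
       main = sprintf("Perceptual space (C = %.3f)", x$C_spline), ...)
  graphics::points(x$configuration$points, pch = 19)
  graphics::text(x$configuration$points, labels = x$configuration$labels,
                 pos = 3, cex = 0.7)
  invisible(x)
}

check_rating_trials <- function(trials) {
  need <- c("participant_id", "tone_a", "tone_b", "rating")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop("trials must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(trials$rating)) ||
      any(trials$rating < 0 | trials$rating > 5))
    stop("ratings must lie in [0, 5]", call. = FALSE)
  invisible(trials)
}
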