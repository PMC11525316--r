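## Seeded generators for synthetic similarity-rating and reproduction-trial
## datasets with the statistical structure the analysis pipeline assumes.

# tone degrees rated by each participant set (24-degree grid, interleaved),
# sharing three anchors 120 degrees apart
default_tone_sets <- function() {
  list(set1 = c(48, 96, 120, 168, 216, 240, 288, 336, 360),
       set2 = c(24, 72, 120, 144, 192, 240, 264, 312, 360))
}

#' Generate a synthetic similarity-rating study
#'
#' Emulates a two-set circular similarity-judgment design: each participant
#' rates every unordered pair of their set's nine tones eight times and each
#' tone against itself twice, on a 0--5 Likert scale. The mean rating
#' declines linearly with circular angular distance,
#' \eqn{\mu(\Delta) = a - b\Delta}; a Gaussian noise term is added and the
#' result rounded and clamped to the scale. The defaults \code{a = 4.274},
#' \code{b = 0.01226} put the mean at 3.98 for a 24-degree pair and 1.92 for
#' a 192-degree pair. Self-similarity ratings are drawn near the top of the
#' scale (Normal(4.8, 0.3), clamped); \code{n_low_self} participants per set
#' can be planted with poor self-similarity (Normal(3, 0.5)) so the
#' exclusion rule has something to catch.
#'
#' @param tone_sets List of numeric vectors of tone degrees, one per
#'   participant set.
#' @param n_per_set Participants per set.
#' @param a,b Intercept and slope of mean rating vs. circular distance
#'   (rating units; degrees^-1).
#' @param noise_sd SD of the Gaussian rating noise (0.7 by default).
#' @param n_low_self Participants per set planted to fail the
#'   self-similarity exclusion rule.
#' @param n_reps Ratings per unordered non-identical pair (default 8).
#' @param n_self Self-comparison ratings per tone (default 2).
#' @param discretize Round ratings to the integer Likert scale (default
#'   \code{TRUE}, as in a real study). \code{FALSE} keeps the real-valued
#'   ratings, useful with \code{noise_sd = 0} to feed the pipeline an exact,
#'   quantization-free distance structure.
#' @param seed Integer seed.
#' @return Data frame of rating trials: \code{participant_id},
#'   \code{tone_a}, \code{tone_b}, \code{rating}, \code{set},
#'   \code{order_index}.
#' @export
gen_similarity_study <- function(tone_sets = default_tone_sets(),
                                 n_per_set = 14,
                                 a = 4.274, b = 0.01226,
                                 noise_sd = 0.7,
                                 n_low_self = 2,
                                 n_reps = 8, n_self = 2,
                                 discretize = TRUE,
                                 seed = 1) {
  stopifnot(a <= 5, noise_sd >= 0, n_per_set >= 1, n_low_self <= n_per_set)
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (s in seq_along(tone_sets)) {
    tones <- tone_sets[[s]]
    pairs <- utils::combn(tones, 2)
    for (p in seq_len(n_per_set)) {
      pid <- pid + 1
      id <- sprintf("P%02d", pid)
      low_self <- p <= n_low_self
      ta <- c(rep(pairs[1, ], each = n_reps), rep(tones, each = n_self))
      tb <- c(rep(pairs[2, ], each = n_reps), rep(tones, each = n_self))
      d <- circ_dist(ta, tb)
      mu <- ifelse(ta == tb,
                   if (low_self) stats::rnorm(length(ta), 3, 0.5)
                   else stats::rnorm(length(ta), 4.8, 0.3),
                   a - b * d + stats::rnorm(length(ta), 0, noise_sd))
      rating <- pmin(5, pmax(0, if (discretize) floor(mu + 0.5) else mu))
      ord <- sample.int(length(ta))
      rows[[pid]] <- data.frame(
        participant_id = id, tone_a = ta[ord], tone_b = tb[ord],
        rating = if (discretize) as.integer(rating[ord]) else rating[ord],
        set = s,
        order_index = seq_along(ta), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic reproduction-trial dataset
#'
#' Emulates a delayed-estimation session on the circular tone space:
#' \code{n_blocks} blocks of \code{trials_per_block} trials per participant
#' with an equal number of trials per set size, targets uniform on 1--360.
#' Set-size-1 errors are drawn from the standard mixture; set-size-2 trials
#' get one uniformly placed non-target and errors from the swap model; the
#' probed serial position is chosen uniformly.
#'
#' @param params Named list of mixture parameters per set size; each element
#'   is \code{list(g =, sd =)} (standard, set size 1) or
#'   \code{list(g =, beta =, sd =)} (swap, set size 2). Defaults to guess
#'   rate 0.18 / SD 29.1 degrees at set size 1 and guess 0.18 / swap 0.11 /
#'   SD 30.65 degrees at set size 2.
#' @param n_participants Number of participants.
#' @param n_blocks Blocks per participant (default 4).
#' @param trials_per_block Trials per block (default 50; split equally over
#'   set sizes).
#' @param seed Integer seed.
#' @return Data frame with columns \code{participant_id}, \code{block},
#'   \code{set_size}, \code{serial_position}, \code{target_deg},
#'   \code{response_deg}, \code{nontarget_deg} (\code{NA} at set size 1).
#' @export
gen_reproduction_study <- function(params = list(
                                     `1` = list(g = 0.18, sd = 29.1),
                                     `2` = list(g = 0.18, beta = 0.11,
                                                sd = 30.65)),
                                   n_participants = 18,
                                   n_blocks = 4,
                                   trials_per_block = 50,
                                   seed = 1) {
  set_sizes <- as.integer(names(params))
  stopifnot(length(set_sizes) >= 1, trials_per_block %% length(set_sizes) == 0)
  for (p in params) {
    stopifnot(p$g >= 0, p$sd > 0)
    if (!is.null(p$beta)) stopifnot(p$beta >= 0, p$g + p$beta <= 1)
  }
  set.seed(seed)
  per_ss <- trials_per_block %/% length(set_sizes)
  rows <- list(); r <- 0
  for (pp in seq_len(n_participants)) {
    id <- sprintf("S%02d", pp)
    for (blk in seq_len(n_blocks)) {
      for (ss in set_sizes) {
        r <- r + 1
        par <- params[[as.character(ss)]]
        target <- stats::runif(per_ss, 1, 360)
        if (ss == 1 || is.null(par$beta)) {
          err <- simulate_standard(per_ss, par$g, par$sd)
          nt <- rep(NA_real_, per_ss)
          spos <- rep(1L, per_ss)
        } else {
          nt <- stats::runif(per_ss, 1, 360)
          err <- simulate_swap(per_ss, par$g, par$beta, par$sd,
                               wrap_angle(nt - target))$error
          spos <- sample.int(ss, per_ss, replace = TRUE)
        }
        rows[[r]] <- data.frame(
          participant_id = id, block = blk, set_size = ss,
          serial_position = spos, target_deg = target,
          response_deg = ((target + err - 1) %% 360) + 1,
          nontarget_deg = nt, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  # shuffle trial order within each block, as in a randomized session
  out <- out[order(out$participant_id, out$block,
                   stats::runif(nrow(out))), ]
  rownames(out) <- NULL
  out
}
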