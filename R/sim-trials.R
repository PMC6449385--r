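#' Generate a pseudo-randomized conflict-task trial sequence
#'
#' Builds a block of control and interference trials with emotional-image
#' valence categories and response fingers assigned in counterbalanced
#' fashion, then shuffles under the task's interleaving constraint: no more
#' than two trials in a row may share the same valence category, the same
#' interference level, or the same response finger. The constraint keeps
#' the trial stream unpredictable so that cognitive control cannot be
#' engaged prospectively.
#'
#' @param n_control,n_interference number of trials of each type.
#' @param valences character vector of valence categories to cycle through
#'   (default positive / neutral / negative).
#' @param seed integer seed; fixed seed gives an identical sequence.
#' @param max_sweeps bound on repair sweeps before the constraint set is
#'   declared infeasible (prevents an infinite loop for impossible inputs,
#'   e.g. a single-type block of three or more trials).
#' @return data.frame with one row per trial: `trial_index`, `interference`
#'   (factor control/interference), `valence_cat`, `valence` and `arousal`
#'   (1-9 ratings), `target_finger` (1-3).
#' @examples
#' seq1 <- generate_trial_sequence(72, 72, seed = 1)
#' nrow(seq1)  # 144
#' @export
generate_trial_sequence <- function(n_control, n_interference,
                                    valences = c("negative", "neutral",
                                                 "positive"),
                                    seed = 1L,
                                    max_sweeps = 3000L) {
  n <- n_control + n_interference
  if (n == 0) {
    return(data.frame(trial_index = integer(0), interference = factor(),
                      valence_cat = character(0), valence = numeric(0),
                      arousal = numeric(0), target_finger = integer(0)))
  }
  if (n_control < 0 || n_interference < 0) stop("negative trial counts")
  if (length(valences) == 0) valences <- "neutral"

  set.seed(seed)

  interference <- rep(c("control", "interference"),
                      c(n_control, n_interference))
  val_cat <- rep_len(valences, n)  # balanced overall; shuffled below
  finger <- rep_len(1:3, n)

  ord <- sample.int(n)
  a1 <- interference[ord]
  a2 <- val_cat[ord]
  a3 <- as.character(finger[ord])

  viol_count <- function(v) {
    r <- rle(v)
    sum(pmax(0L, r$lengths - 2L))  # each extra element of a long run
  }
  total_viol <- function() viol_count(a1) + viol_count(a2) + viol_count(a3)
  first_viol <- function() {
    for (v in list(a1, a2, a3)) {
      r <- rle(v)
      bad <- which(r$lengths >= 3)
      if (length(bad)) return(cumsum(r$lengths)[bad[1]])
    }
    0L
  }
  swap <- function(i, j) {
    t1 <- a1[i]; a1[i] <<- a1[j]; a1[j] <<- t1
    t2 <- a2[i]; a2[i] <<- a2[j]; a2[j] <<- t2
    t3 <- a3[i]; a3[i] <<- a3[j]; a3[j] <<- t3
  }

  # greedy repair: swap the trial ending a run of three with a position
  # chosen so the total violation count strictly decreases
  cur <- total_viol()
  sweep <- 0L
  while (cur > 0) {
    sweep <- sweep + 1L
    if (sweep > max_sweeps) {
      stop("infeasible trial-sequence constraints: ", cur,
           " run-of-three violation(s) remain after ", max_sweeps,
           " repair sweeps")
    }
    i <- first_viol()
    improved <- FALSE
    plateau_j <- NA_integer_
    for (j in sample.int(n, min(n, 80L))) {
      if (j == i) next
      swap(i, j)
      new <- total_viol()
      if (new < cur) { cur <- new; improved <- TRUE; break }
      if (new == cur && is.na(plateau_j)) plateau_j <- j
      swap(i, j)
    }
    if (!improved) {
      if (!is.na(plateau_j)) {
        swap(i, plateau_j)  # sideways move to escape the plateau
      } else {
        ro <- sample.int(n)
        a1 <- a1[ro]; a2 <- a2[ro]; a3 <- a3[ro]
        cur <- total_viol()
      }
    }
  }
  df <- data.frame(interference = a1, valence_cat = a2,
                   target_finger = as.integer(a3),
                   stringsAsFactors = FALSE)

  # per-trial numeric ratings drawn around category-level means
  means <- c(negative = 2.5, neutral = 5, positive = 7.5)
  mu <- means[df$valence_cat]
  mu[is.na(mu)] <- 5
  df$valence <- pmin(9, pmax(1, stats::rnorm(n, mu, 0.7)))
  df$arousal <- pmin(9, pmax(1, stats::rnorm(n, 5, 1.5)))
  df$trial_index <- seq_len(n)
  df$interference <- factor(df$interference,
                            levels = c("control", "interference"))
  rownames(df) <- NULL
  df[, c("trial_index", "interference", "valence_cat", "valence",
         "arousal", "target_finger")]
}

#' Count run-of-three constraint violations in a trial sequence
#'
#' Exhaustively scans every window of three consecutive trials and counts
#' windows in which the valence category, the interference level, or the
#' target finger is identical across all three.
#'
#' @param trials data.frame as returned by [generate_trial_sequence()].
#' @return integer count (0 for a valid sequence).
#' @export
count_sequence_violations <- function(trials) {
  n <- nrow(trials)
  if (n < 3) return(0L)
  bad <- 0L
  for (i in 3:n) {
    w <- (i - 2):i
    for (col in c("interference", "valence_cat", "target_finger")) {
      v <- as.character(trials[[col]][w])
      if (v[1] == v[2] && v[2] == v[3]) bad <- bad + 1L
    }
  }
  bad
}

#' Split rated images into two matched sets
#'
#' Divides an even number of images into two equal sets while keeping the
#' sets matched on their ratings: images are rank-ordered by valence,
#' consecutive pairs are formed, and one member of each pair goes to each
#' set (alternating which set receives the lower-ranked member). The
#' initial split is then refined by deterministic first-improvement local
#' search: single cross-set swaps are applied while they reduce the
#' objective, the mean squared difference between rank-matched image
#' ratings across the two sets.
#'
#' @param ratings data.frame or matrix with columns `valence` and `arousal`
#'   (arousal optional).
#' @return list with integer index vectors `set1` and `set2` and the
#'   achieved `objective`.
#' @examples
#' r <- data.frame(valence = runif(144, 1, 9), arousal = runif(144, 1, 9))
#' sp <- split_images(r)
#' length(sp$set1)  # 72
#' @export
split_images <- function(ratings) {
  ratings <- as.data.frame(ratings)
  n <- nrow(ratings)
  if (n %% 2 != 0) stop("split_images requires an even number of images")
  if (n == 0) return(list(set1 = integer(0), set2 = integer(0),
                          objective = 0))
  ord <- order(ratings$valence)
  set1 <- integer(0); set2 <- integer(0)
  flip <- FALSE
  for (k in seq(1, n, by = 2)) {
    a <- ord[k]; b <- ord[k + 1]
    if (flip) { t <- a; a <- b; b <- t }
    set1 <- c(set1, a); set2 <- c(set2, b)
    flip <- !flip
  }
  obj <- split_objective(ratings, set1, set2)
  # first-improvement local search over single cross-set swaps
  repeat {
    improved <- FALSE
    for (i in seq_along(set1)) {
      for (j in seq_along(set2)) {
        s1 <- set1; s2 <- set2
        s1[i] <- set2[j]; s2[j] <- set1[i]
        cand <- split_objective(ratings, s1, s2)
        if (cand < obj - 1e-12) {
          set1 <- s1; set2 <- s2; obj <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(set1 = sort(set1), set2 = sort(set2), objective = obj)
}

#' Matching objective for an image split
#'
#' Mean squared difference between rank-matched ratings of two image sets,
#' where each set is rank-ordered by valence and the i-th images are
#' paired. Valence and (when present) arousal differences both contribute.
#'
#' @param ratings ratings table (see [split_images()]).
#' @param set1,set2 integer index vectors of equal length.
#' @return scalar objective (0 = perfectly matched).
#' @export
split_objective <- function(ratings, set1, set2) {
  ratings <- as.data.frame(ratings)
  stopifnot(length(set1) == length(set2))
  o1 <- set1[order(ratings$valence[set1])]
  o2 <- set2[order(ratings$valence[set2])]
  d2 <- (ratings$valence[o1] - ratings$valence[o2])^2
  if (!is.null(ratings$arousal)) {
    d2 <- d2 + (ratings$arousal[o1] - ratings$arousal[o2])^2
  }
  mean(d2)
}
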