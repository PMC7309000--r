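#' Inertia-weight schedule for PSO
#'
#' Three laws for the inertia weight over iterations `t = 0..tmax`:
#' `"constant"` (always `ws`), `"LDW"` (linear decrease from `ws` to `we`),
#' and `"MLDW"` -- a three-stage law that decreases linearly from `ws` to a
#' plateau `wm` over `[0, t1]`, holds `wm` on `(t1, t2]`, then decreases
#' linearly to `we` on `(t2, tmax]`. The MLDW law is continuous at `t1` and
#' `t2` by construction.
#'
#' @param kind `"MLDW"`, `"LDW"`, or `"constant"`.
#' @param ws initial inertia weight.
#' @param we final inertia weight.
#' @param wm plateau weight (MLDW only), `we <= wm <= ws`.
#' @param t1,t2 plateau boundaries (MLDW only), `0 < t1 < t2 < tmax`.
#' @param tmax iteration budget.
#' @return An object of class `inertia_schedule`.
#' @seealso [mldw_strategy()] for the named strategies w0-w6.
#' @export
inertia_schedule <- function(kind = c("MLDW", "LDW", "constant"),
                             ws = 0.9, we = 0.4, wm = NULL,
                             t1 = NULL, t2 = NULL, tmax = 50) {
  kind <- match.arg(kind)
  if (kind == "MLDW") {
    if (is.null(wm) || is.null(t1) || is.null(t2)) {
      stop("MLDW schedule needs wm, t1 and t2")
    }
    stopifnot(we <= wm, wm <= ws, 0 < t1, t1 < t2, t2 < tmax)
  }
  stopifnot(0 <= we, we <= ws, ws <= 1, tmax > 0)
  structure(list(kind = kind, ws = ws, we = we, wm = wm,
                 t1 = t1, t2 = t2, tmax = tmax),
            class = "inertia_schedule")
}

#' Named multi-stage inertia strategies
#'
#' The six studied MLDW parameterizations `w1`-`w6` (all with
#' `ws = 0.9`, `we = 0.4`, `tmax = 50`) plus the plain linearly-decreasing
#' baseline `w0`:
#'
#' | strategy | w1 | w2 | w3 | w4 | w5 | w6 |
#' |----------|----|----|----|----|----|----|
#' | wm | 0.8 | 0.8 | 0.65 | 0.65 | 0.5 | 0.5 |
#' | t1 | 10 | 20 | 10 | 20 | 10 | 20 |
#' | t2 | 40 | 30 | 40 | 30 | 40 | 30 |
#'
#' The stage boundaries in the table are defined for the reference budget
#' `tmax = 50`; for a different budget they are rescaled proportionally so
#' the schedule keeps its shape.
#'
#' @param name one of `"w0"` ... `"w6"`.
#' @param tmax iteration budget.
#' @return An [inertia_schedule()].
#' @export
mldw_strategy <- function(name = "w6", tmax = 50) {
  tab <- list(w1 = c(0.80, 10, 40), w2 = c(0.80, 20, 30),
              w3 = c(0.65, 10, 40), w4 = c(0.65, 20, 30),
              w5 = c(0.50, 10, 40), w6 = c(0.50, 20, 30))
  if (name == "w0") return(inertia_schedule("LDW", tmax = tmax))
  p <- tab[[name]]
  if (is.null(p)) stop("unknown strategy '", name, "' (use w0-w6)")
  inertia_schedule("MLDW", wm = p[1], t1 = p[2] * tmax / 50,
                   t2 = p[3] * tmax / 50, tmax = tmax)
}

#' Evaluate an inertia schedule at iteration t
#'
#' @param schedule an [inertia_schedule()].
#' @param t iteration (scalar or vector), `0 <= t <= tmax`.
#' @return inertia weight(s).
#' @examples
#' inertia_weight(mldw_strategy("w6"), c(0, 25, 50))  # 0.9 0.5 0.4
#' @export
inertia_weight <- function(schedule, t) {
  stopifnot(inherits(schedule, "inertia_schedule"))
  if (any(t < 0 | t > schedule$tmax)) {
    stop("t must lie in [0, tmax]")
  }
  s <- schedule
  switch(s$kind,
    constant = rep(s$ws, length(t)),
    LDW = (s$ws - s$we) * (s$tmax - t) / s$tmax + s$we,
    MLDW = ifelse(t <= s$t1,
                  (s$ws - s$wm) * (s$t1 - t) / s$t1 + s$wm,
           ifelse(t <= s$t2, s$wm,
                  (s$wm - s$we) * (s$tmax - t) / (s$tmax - s$t2) + s$we))
  )
}

#' Decode a particle position into a feature mask
#'
#' A feature is selected when its position component strictly exceeds the
#' threshold. If no component exceeds it, the single largest component is
#' selected so the mask is never empty.
#'
#' @param position numeric position vector.
#' @param theta selection threshold (> 0 in normal use).
#' @return logical mask of the same length.
#' @export
decode_mask <- function(position, theta = 0.8) {
  mask <- position > theta
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' One PSO velocity update
#'
#' Componentwise `v' = w v + C1 R1 (pbest - x) + C2 R2 (gbest - x)`, clamped
#' to `[-clamp, clamp]`. `r1`/`r2` default to fresh uniform(0, 1) draws per
#' component; passing them explicitly makes the update a pure function for
#' testing.
#'
#' @param velocity,position,pbest,gbest conformable numeric vectors.
#' @param w inertia weight.
#' @param c1,c2 acceleration coefficients.
#' @param clamp velocity clamp (absolute value).
#' @param r1,r2 optional uniform random vectors.
#' @return the new velocity vector.
#' @export
update_velocity <- function(velocity, position, pbest, gbest, w,
                            c1 = 2, c2 = 2, clamp = 0.4,
                            r1 = stats::runif(length(position)),
                            r2 = stats::runif(length(position))) {
  v <- w * velocity + c1 * r1 * (pbest - position) + c2 * r2 * (gbest - position)
  pmin(pmax(v, -clamp), clamp)
}

#' One PSO position update
#'
#' `x' = x + v`. Positions are deliberately not clamped: with a selection
#' threshold of 0.8 and init range `[0, 1]`, drifting above 1 is what lets
#' roughly half of the features end up selected.
#'
#' @param position,velocity conformable numeric vectors.
#' @return the new position vector.
#' @export
update_position <- function(position, velocity) position + velocity

# stratified k-fold assignment; per-class counts across folds differ by <= 1
stratified_folds <- function(labels, k, shuffle = TRUE) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has fewer than k = ", k, " members")
    }
    if (shuffle) idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# linear-SVM cross-validated error for a masked feature set, using a fixed
# fold assignment so every mask is scored on identical splits
masked_cv_error <- function(x, y, mask, fold) {
  err <- 0L
  for (f in unique(fold)) {
    tr <- fold != f
    fit <- e1071::svm(x[tr, mask, drop = FALSE], y[tr],
                      kernel = "linear", cost = 1, scale = FALSE,
                      type = "C-classification")
    pred <- stats::predict(fit, x[!tr, mask, drop = FALSE])
    err <- err + sum(pred != y[!tr])
  }
  err / length(y)
}

#' Wrapper fitness: cross-validated classification error of a mask
#'
#' Stratified inner k-fold cross-validation of a linear soft-margin SVM
#' (cost 1) restricted to the masked feature columns; returns the pooled
#' error rate in `[0, 1]`. Deterministic given `seed` (which fixes the fold
#' assignment).
#'
#' @param mask logical feature mask (>= 1 selected).
#' @param features trials x features numeric matrix.
#' @param labels per-trial class labels (>= 2 classes).
#' @param inner_folds number of folds.
#' @param seed RNG seed for the fold assignment.
#' @return error rate in `[0, 1]`.
#' @export
fitness_error <- function(mask, features, labels, inner_folds = 3, seed = 1) {
  if (!any(mask)) stop("mask selects no features")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least two classes")
  with_seed(seed, {
    fold <- stratified_folds(labels, inner_folds)
    masked_cv_error(as.matrix(features), y, mask, fold)
  })
}

#' Wrapper feature selection by particle swarm optimization
#'
#' A swarm of `n_particles` real-valued particles (one dimension per feature
#' column) searches for the mask minimizing the inner cross-validated SVM
#' error ([fitness_error()]). Positions are initialized uniformly in
#' `init_range` and velocities in `[-0.1, 0.1]`; each iteration every
#' particle's decoded mask is scored, personal and global bests are updated
#' under strict improvement (ties keep the incumbent), the inertia weight is
#' taken from `schedule`, and velocities/positions are updated with fresh
#' uniform draws per component. One seeded random stream is consumed in a
#' fixed documented order (init positions, init velocities, then per
#' iteration per particle R1 then R2), so runs are bitwise reproducible.
#'
#' @param features trials x features numeric matrix.
#' @param labels per-trial class labels.
#' @param schedule an [inertia_schedule()]; its `tmax` is the iteration
#'   budget.
#' @param n_particles swarm size.
#' @param c1,c2 acceleration coefficients.
#' @param theta selection threshold for [decode_mask()].
#' @param velocity_clamp componentwise velocity clamp.
#' @param init_range position initialization range.
#' @param inner_folds folds for the fitness cross-validation.
#' @param seed RNG seed.
#' @return list of class `selection_result`: `mask`, `gbest_position`,
#'   `gbest_fitness`, `history` (data frame with iteration, inertia weight,
#'   gbest fitness, selected count), and `gbest_trace` (iterations x F matrix
#'   of the best position after each iteration, enabling evaluation at
#'   intermediate budgets).
#' @export
select_features <- function(features, labels, schedule = mldw_strategy("w6"),
                            n_particles = 20, c1 = 2, c2 = 2, theta = 0.8,
                            velocity_clamp = 0.4, init_range = c(0, 1),
                            inner_folds = 3, seed = 1) {
  features <- as.matrix(features)
  nf <- ncol(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (min(table(y)) < 2) stop("need at least two trials per class")
  tmax <- schedule$tmax
  with_seed(seed, {
    fold <- stratified_folds(labels, inner_folds)
    score <- function(pos) {
      masked_cv_error(features, y, decode_mask(pos, theta), fold)
    }
    pos <- matrix(stats::runif(n_particles * nf, init_range[1], init_range[2]),
                  n_particles, nf, byrow = TRUE)
    vel <- matrix(stats::runif(n_particles * nf, -0.1, 0.1),
                  n_particles, nf, byrow = TRUE)
    pbest <- pos
    pbest_fit <- apply(pos, 1, score)
    g <- which.min(pbest_fit)
    gbest <- pos[g, ]
    gbest_fit <- pbest_fit[g]
    history <- data.frame(iter = seq_len(tmax), w = NA_real_,
                          gbest_fitness = NA_real_, n_selected = NA_integer_)
    trace <- matrix(NA_real_, tmax, nf)
    for (t in seq_len(tmax)) {
      w <- inertia_weight(schedule, t)
      for (i in seq_len(n_particles)) {
        r1 <- stats::runif(nf)
        r2 <- stats::runif(nf)
        vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest,
                                    w, c1, c2, velocity_clamp, r1, r2)
        pos[i, ] <- update_position(pos[i, ], vel[i, ])
        fit <- score(pos[i, ])
        if (fit < pbest_fit[i]) {
          pbest_fit[i] <- fit
          pbest[i, ] <- pos[i, ]
        }
        if (fit < gbest_fit) {
          gbest_fit <- fit
          gbest <- pos[i, ]
        }
      }
      history$w[t] <- w
      history$gbest_fitness[t] <- gbest_fit
      history$n_selected[t] <- sum(decode_mask(gbest, theta))
      trace[t, ] <- gbest
    }
    structure(list(mask = decode_mask(gbest, theta), gbest_position = gbest,
                   gbest_fitness = gbest_fit, history = history,
                   gbest_trace = trace, theta = theta,
                   schedule = schedule, seed = seed),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features, gbest CV error %.4f (%s, tmax=%d)\n",
              sum(x$mask), length(x$mask), x$gbest_fitness,
              x$schedule$kind, x$schedule$tmax))
  invisible(x)
}

#' Relief filter feature selection
#'
#' Classic Relief weights: for every instance, the nearest same-class hit and
#' nearest other-class miss are found by Euclidean distance on range-scaled
#' features, and each feature's weight accumulates the (range-scaled) miss
#' minus hit distance along that coordinate. The top
#' `floor(keep_fraction * F)` features by weight are selected; weight ties
#' break deterministically by column index.
#'
#' @param features trials x features numeric matrix.
#' @param labels per-trial class labels (>= 2 per class).
#' @param keep_fraction fraction of features to keep, in `(0, 1]`.
#' @return logical mask with exactly `floor(keep_fraction * ncol(features))`
#'   (at least 1) selected features; weights attached as attribute
#'   `"weights"`.
#' @export
relief_select <- function(features, labels, keep_fraction = 0.5) {
  features <- as.matrix(features)
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  y <- as.vector(labels)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least two classes with two or more trials each")
  }
  rng <- apply(features, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  z <- sweep(sweep(features, 2, apply(features, 2, min)), 2, rng, "/")
  n <- nrow(z)
  d2 <- as.matrix(stats::dist(z))^2
  diag(d2) <- Inf
  wts <- numeric(ncol(z))
  for (i in seq_len(n)) {
    hits <- which(y == y[i])
    miss <- which(y != y[i])
    h <- hits[which.min(d2[i, hits])]
    m <- miss[which.min(d2[i, miss])]
    wts <- wts + (abs(z[i, ] - z[m, ]) - abs(z[i, ] - z[h, ])) / n
  }
  keep <- max(1L, floor(keep_fraction * ncol(z)))
  ord <- order(wts, -seq_along(wts), decreasing = TRUE)
  mask <- logical(ncol(z))
  mask[ord[seq_len(keep)]] <- TRUE
  attr(mask, "weights") <- wts
  mask
}
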