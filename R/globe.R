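#' Target geodesic distances for the spherical layout
#'
#' Maps gene-set dissimilarity linearly onto geodesic distance: a pathway
#' pair with similarity \eqn{s} gets target distance
#' \eqn{(1 - s) \times} \code{max_arc}. Identical pathways are targeted at
#' distance 0 and disjoint pathways at \code{max_arc} (antipodal with the
#' default \code{pi}).
#'
#' @param x A \code{\link{pathway_collection}} with at least 2 pathways.
#' @param max_arc Geodesic distance assigned to fully disjoint pairs
#'   (radians; default \code{pi}).
#' @return A \code{\link[stats]{dist}} object over pathway ids.
#' @export
target_distances <- function(x, max_arc = pi) {
  stopifnot(inherits(x, "pathway_collection"))
  if (length(x) < 2L) {
    stop("target distances need at least 2 pathways", call. = FALSE)
  }
  s <- similarity_matrix(x)
  if (anyNA(s)) {
    stop("similarity is undefined for pathway pairs with empty gene sets",
         call. = FALSE)
  }
  d <- (1 - s) * max_arc
  stats::as.dist(d)
}

#' Embed pathways on a sphere preserving gene-set dissimilarity
#'
#' Places each pathway on the unit sphere and minimizes a normalized
#' Kruskal-type stress between realized geodesic distances and the targets of
#' \code{\link{target_distances}}:
#' \deqn{\sigma = \sum_{i<j} (g_{ij} - d_{ij})^2 / \sum_{i<j} d_{ij}^2}
#' with \eqn{g_{ij} = \arccos(x_i \cdot x_j)}. Optimization is projected
#' gradient descent on the sphere with step halving whenever a step would
#' increase stress, so recorded stress is non-increasing; several random
#' restarts are run and the best kept. Initial positions are drawn uniformly
#' on the sphere from the given seed, making the layout fully reproducible.
#'
#' @param x A \code{\link{pathway_collection}} with at least 3 pathways.
#' @param seed Integer RNG seed controlling the random initializations.
#' @param n_iterations Maximum gradient iterations per restart (default 500).
#' @param max_arc Passed to \code{\link{target_distances}}.
#' @param n_starts Number of random restarts (default 4).
#' @return An object of class \code{"sphere_layout"}: \code{coordinates}
#'   (pathways x 3 unit-norm matrix), \code{target} (the target
#'   \code{dist}), \code{stress}, \code{stress_trace} (stress after each
#'   accepted iteration of the best restart, starting from its initial
#'   value), \code{seed}, \code{n_iterations}, \code{max_arc}.
#' @export
embed_sphere <- function(x, seed, n_iterations = 500L, max_arc = pi,
                         n_starts = 4L) {
  stopifnot(inherits(x, "pathway_collection"))
  n <- length(x)
  if (n < 3L) stop("spherical layout needs at least 3 pathways", call. = FALSE)
  stopifnot(n_iterations >= 0L, n_starts >= 1L)
  D <- as.matrix(target_distances(x, max_arc))
  denom <- sum(D[upper.tri(D)]^2)
  if (denom == 0) denom <- 1  # all-identical collection: any layout has stress 0

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  best <- NULL
  for (start in seq_len(n_starts)) {
    X <- matrix(stats::rnorm(3L * n), ncol = 3L)
    X <- X / sqrt(rowSums(X^2))
    run <- descend_sphere(X, D, denom, n_iterations)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  rownames(best$X) <- pathway_ids(x)
  colnames(best$X) <- c("x", "y", "z")
  structure(list(coordinates = best$X,
                 target = stats::as.dist(D),
                 stress = best$stress,
                 stress_trace = best$trace,
                 seed = as.integer(seed),
                 n_iterations = n_iterations,
                 max_arc = max_arc),
            class = "sphere_layout")
}

sphere_stress <- function(X, D, denom) {
  G <- geodesic_matrix(X)
  sum((G[upper.tri(G)] - D[upper.tri(D)])^2) / denom
}

geodesic_matrix <- function(X) {
  C <- tcrossprod(X)
  C[C > 1] <- 1; C[C < -1] <- -1
  acos(C)
}

# projected gradient descent with backtracking; returns unit-norm X, final
# stress and the monotone stress trace
descend_sphere <- function(X, D, denom, n_iterations) {
  stress <- sphere_stress(X, D, denom)
  trace <- stress
  step <- 0.1
  for (it in seq_len(n_iterations)) {
    C <- tcrossprod(X)
    C[C > 1] <- 1; C[C < -1] <- -1
    G <- acos(C)
    E <- G - D
    diag(E) <- 0
    # d(acos c)/dc = -1/sqrt(1-c^2); guard the poles
    W <- E / sqrt(pmax(1 - C^2, 1e-12))
    grad <- (-2 / denom) * (W %*% X)
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < 1e-14) break
    improved <- FALSE
    for (half in 0:40) {
      Xn <- X - (step / 2^half) * grad
      Xn <- Xn / sqrt(rowSums(Xn^2))
      s_new <- sphere_stress(Xn, D, denom)
      if (s_new < stress) {
        X <- Xn
        stress <- s_new
        step <- step / 2^half * 1.5  # gently re-expand after backtracking
        improved <- TRUE
        break
      }
    }
    if (!improved) break
    trace <- c(trace, stress)
  }
  list(X = X, stress = stress, trace = trace)
}

#' @export
print.sphere_layout <- function(x, ...) {
  cat("<sphere_layout> ", nrow(x$coordinates), " pathways on the unit sphere\n",
      "  stress = ", signif(x$stress, 6), " after ",
      length(x$stress_trace) - 1L, " accepted iterations (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Latitude/longitude view of a spherical layout
#'
#' @param layout A \code{"sphere_layout"}.
#' @return Data frame with \code{pathway_id}, \code{lat_deg} (-90..90),
#'   \code{lon_deg} (-180..180).
#' @export
layout_latlon <- function(layout) {
  stopifnot(inherits(layout, "sphere_layout"))
  X <- layout$coordinates
  data.frame(pathway_id = rownames(X),
             lat_deg = asin(pmin(pmax(X[, 3L], -1), 1)) * 180 / pi,
             lon_deg = atan2(X[, 2L], X[, 1L]) * 180 / pi,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
plot.sphere_layout <- function(x, ...) {
  ll <- layout_latlon(x)
  plot(ll$lon_deg, ll$lat_deg, xlim = c(-180, 180), ylim = c(-90, 90),
       xlab = "longitude (deg)", ylab = "latitude (deg)",
       main = "pathway globe (equirectangular)", pch = 19, ...)
  invisible(x)
}
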