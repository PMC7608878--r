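#' Mixture-of-squared-exponential intensity function
#'
#' Intensity surface for an inhomogeneous Poisson process over a rectangular
#' field: `lambda(s) = sum_i C_i exp{-(sx - cx_i)^2 / h_i^2 - (sy - cy_i)^2 /
#' l_i^2}` (note the denominators are `h^2`, `l^2` with no factor 2). The
#' amplitudes `C_i` are in trees per square metre; `(cx, cy)` are the kernel
#' centres and `(h, l)` the length scales in metres. Infinite `h` and `l` are
#' allowed and give a spatially constant component, i.e. a homogeneous
#' process.
#'
#' @param components Data frame with columns `C`, `cx`, `cy`, `h`, `l`; may
#'   have zero rows (zero intensity everywhere).
#' @param domain Field rectangle `c(x0, x1, y0, y1)` in metres.
#' @return An object of class `intensity_mixture`.
#' @examples
#' mix <- intensity_mixture(
#'   data.frame(C = c(1.0, 0.6), cx = c(5, 15), cy = c(5, 15),
#'              h = c(3, 3), l = c(2, 2)),
#'   domain = c(0, 20, 0, 20))
#' intensity(mix, 5, 5)
#' @export
intensity_mixture <- function(components, domain) {
  components <- tibble::as_tibble(components)
  need <- c("C", "cx", "cy", "h", "l")
  if (nrow(components) > 0 && !all(need %in% names(components))) {
    stop("components must have columns C, cx, cy, h, l", call. = FALSE)
  }
  if (nrow(components) == 0) {
    components <- tibble::tibble(C = numeric(0), cx = numeric(0),
                                 cy = numeric(0), h = numeric(0), l = numeric(0))
  }
  stopifnot(all(components$C >= 0), all(components$h > 0), all(components$l > 0))
  domain <- as.numeric(domain)
  if (length(domain) != 4 || domain[2] <= domain[1] || domain[4] <= domain[3]) {
    stop("domain must be c(x0, x1, y0, y1) with x1 > x0 and y1 > y0",
         call. = FALSE)
  }
  structure(list(components = components, domain = domain),
            class = "intensity_mixture")
}

#' Homogeneous intensity over a rectangle
#'
#' Convenience wrapper: a single spatially constant component of amplitude
#' `C` (trees per square metre).
#'
#' @param C Constant intensity.
#' @param domain Field rectangle `c(x0, x1, y0, y1)`.
#' @return An `intensity_mixture`.
#' @export
homogeneous_intensity <- function(C, domain) {
  intensity_mixture(
    tibble::tibble(C = C, cx = 0, cy = 0, h = Inf, l = Inf), domain)
}

#' @export
print.intensity_mixture <- function(x, ...) {
  d <- x$domain
  cat(sprintf("<intensity_mixture> %d component(s) on [%g, %g] x [%g, %g]\n",
              nrow(x$components), d[1], d[2], d[3], d[4]))
  cat(sprintf("  expected count over domain: %.3f\n", intensity_integral(x)))
  invisible(x)
}

#' Evaluate the intensity at points
#'
#' @param mixture An [intensity_mixture()].
#' @param x,y Coordinates (vectorized). `x` may instead be a two-column
#'   matrix or data frame of points, in which case `y` is ignored.
#' @return Numeric vector of intensities (trees per square metre).
#' @export
intensity <- function(mixture, x, y = NULL) {
  stopifnot(inherits(mixture, "intensity_mixture"))
  if (is.null(y)) {
    pts <- as.matrix(as.data.frame(x))
    x <- pts[, 1]
    y <- pts[, 2]
  }
  cmp <- mixture$components
  out <- numeric(length(x))
  for (i in seq_len(nrow(cmp))) {
    ex <- if (is.finite(cmp$h[i])) (x - cmp$cx[i])^2 / cmp$h[i]^2 else 0
    ey <- if (is.finite(cmp$l[i])) (y - cmp$cy[i])^2 / cmp$l[i]^2 else 0
    out <- out + cmp$C[i] * exp(-(ex + ey))
  }
  out
}

# exact integral of one squared-exponential factor over [a, b]
gauss_factor_integral <- function(centre, scale, a, b) {
  if (!is.finite(scale)) return(b - a)
  sqrt(pi) * scale / 2 *
    (pracma::erf((b - centre) / scale) - pracma::erf((a - centre) / scale))
}

#' Integral of the intensity over a rectangle
#'
#' The expected number of points of the process in `domain`. Each
#' squared-exponential component factorizes, so the integral is computed in
#' closed form from the Gaussian error function; a component wholly interior
#' to the domain approaches `C * pi * h * l`.
#'
#' @param mixture An [intensity_mixture()].
#' @param domain Rectangle `c(x0, x1, y0, y1)`; defaults to the mixture's
#'   domain.
#' @return Nonnegative scalar.
#' @export
intensity_integral <- function(mixture, domain = mixture$domain) {
  stopifnot(inherits(mixture, "intensity_mixture"))
  cmp <- mixture$components
  total <- 0
  for (i in seq_len(nrow(cmp))) {
    total <- total + cmp$C[i] *
      gauss_factor_integral(cmp$cx[i], cmp$h[i], domain[1], domain[2]) *
      gauss_factor_integral(cmp$cy[i], cmp$l[i], domain[3], domain[4])
  }
  total
}

#' Sample point locations from the inhomogeneous Poisson process
#'
#' Thinning sampler: a homogeneous process at rate `lambda_max = sum(C_i)`
#' (a global upper bound of the intensity) is drawn by placing
#' `N ~ Poisson(lambda_max * |D|)` points uniformly on the domain, and each
#' point is retained independently with probability
#' `lambda(s) / lambda_max`. The retained set is an exact draw of the
#' process.
#'
#' @param mixture An [intensity_mixture()].
#' @param seed Integer seed; draws are reproducible per seed.
#' @return A tibble with columns `x`, `y` (possibly zero rows).
#' @export
sample_locations <- function(mixture, seed = 1L) {
  stopifnot(inherits(mixture, "intensity_mixture"))
  lambda_max <- sum(mixture$components$C)
  d <- mixture$domain
  area <- (d[2] - d[1]) * (d[4] - d[3])
  if (lambda_max == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  withr::with_seed(as.integer(seed), {
    n <- stats::rpois(1, lambda_max * area)
    if (n == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
    x <- stats::runif(n, d[1], d[2])
    y <- stats::runif(n, d[3], d[4])
    keep <- stats::runif(n) < intensity(mixture, x, y) / lambda_max
    tibble::tibble(x = x[keep], y = y[keep])
  })
}

#' Marginal coordinate distribution of the process
#'
#' Closed-form cumulative distribution function of one coordinate of a point
#' drawn from the normalized intensity (useful for goodness-of-fit checks of
#' the sampler, e.g. Kolmogorov-Smirnov tests).
#'
#' @param mixture An [intensity_mixture()].
#' @param axis `"x"` or `"y"`.
#' @return A vectorized function `F(q)` returning probabilities.
#' @export
intensity_marginal_cdf <- function(mixture, axis = c("x", "y")) {
  axis <- match.arg(axis)
  cmp <- mixture$components
  d <- mixture$domain
  if (axis == "y") {
    cmp <- tibble::tibble(C = cmp$C, cx = cmp$cy, cy = cmp$cx,
                          h = cmp$l, l = cmp$h)
    d <- d[c(3, 4, 1, 2)]
  }
  # weight of component i = C_i * integral of its y factor over the y range
  w <- vapply(seq_len(nrow(cmp)), function(i) {
    cmp$C[i] * gauss_factor_integral(cmp$cy[i], cmp$l[i], d[3], d[4])
  }, numeric(1))
  total <- sum(vapply(seq_len(nrow(cmp)), function(i) {
    w[i] * gauss_factor_integral(cmp$cx[i], cmp$h[i], d[1], d[2])
  }, numeric(1)))
  function(q) {
    q <- pmin(pmax(q, d[1]), d[2])
    vapply(q, function(qq) {
      num <- sum(vapply(seq_len(nrow(cmp)), function(i) {
        w[i] * gauss_factor_integral(cmp$cx[i], cmp$h[i], d[1], qq)
      }, numeric(1)))
      num / total
    }, numeric(1))
  }
}

#' Species specification for forest building
#'
#' Bundles the intensity that places trees of one species with the
#' configuration used to grow each tree: grammar, expansion depth, geometry
#' parameters, branch templates and the leaf-disc radius distribution.
#'
#' @param label Species name.
#' @param mixture An [intensity_mixture()].
#' @param grammar An [lsys_grammar()].
#' @param iterations L-system expansion depth per tree.
#' @param params A [geometry_params()].
#' @param templates List of [make_branch_template()] objects; by default two
#'   templates derived from the species label hash.
#' @param radius_mean,radius_sd Leaf-disc radius distribution (m).
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(label, mixture,
                         grammar = default_grammar(),
                         iterations = 2,
                         params = geometry_params(),
                         templates = NULL,
                         radius_mean = 0.04, radius_sd = 0.008) {
  stopifnot(inherits(mixture, "intensity_mixture"))
  if (is.null(templates)) {
    base <- sum(utf8ToInt(label)) %% 1000L
    templates <- lapply(1:2, function(i) {
      make_branch_template(leaf_count = 20, seed = base + i)
    })
  }
  structure(
    list(label = label, mixture = mixture, grammar = grammar,
         iterations = iterations, params = params, templates = templates,
         radius_mean = radius_mean, radius_sd = radius_sd),
    class = "species_spec"
  )
}

# cross-species spacing rule: walk species in sampling order and delete any
# point of a later species closer than min_spacing to a retained point of an
# earlier species
enforce_spacing <- function(locs_list, min_spacing) {
  kept <- list()
  deleted <- 0L
  for (i in seq_along(locs_list)) {
    cur <- locs_list[[i]]
    if (i > 1 && nrow(cur) > 0) {
      prev <- dplyr::bind_rows(kept)
      if (nrow(prev) > 0) {
        ok <- vapply(seq_len(nrow(cur)), function(k) {
          min(sqrt((prev$x - cur$x[k])^2 + (prev$y - cur$y[k])^2)) >= min_spacing
        }, logical(1))
        deleted <- deleted + sum(!ok)
        cur <- cur[ok, , drop = FALSE]
      }
    }
    kept[[i]] <- cur
  }
  list(locations = kept, deleted = deleted)
}

#' Build a multi-species forest
#'
#' Samples tree locations for each species independently from its intensity,
#' merges the species into one community while enforcing that two trees of
#' different species are at least `min_spacing` apart (the member of an
#' offending cross-species pair belonging to the later-sampled species is
#' deleted, and deletions are reported), and grows a tree at every surviving
#' location via the L-system and template-assembly pipeline.
#'
#' @param species_specs List of [species_spec()] objects (sampling order
#'   matters for the spacing rule).
#' @param min_spacing Minimum cross-species distance in metres.
#' @param seed Master seed; per-species and per-tree sub-seeds are derived
#'   from it.
#' @return An object of class `sim_forest`: a tibble with columns `x`, `y`,
#'   `species` and a `tree` list-column of `sim_tree` objects; attributes
#'   `seed`, `min_spacing`, `deleted`.
#' @export
build_forest <- function(species_specs, min_spacing = 1, seed = 1L) {
  if (inherits(species_specs, "species_spec")) species_specs <- list(species_specs)
  stopifnot(length(species_specs) >= 1,
            all(vapply(species_specs, inherits, logical(1), "species_spec")))
  seed <- as.integer(seed)
  locs_list <- lapply(seq_along(species_specs), function(i) {
    sample_locations(species_specs[[i]]$mixture, seed = derive_seed(seed, i))
  })
  sp <- enforce_spacing(locs_list, min_spacing)
  if (sp$deleted > 0) {
    message(sprintf("spacing rule removed %d tree(s) closer than %g m to an earlier species",
                    sp$deleted, min_spacing))
  }
  rows <- list()
  tree_idx <- 0L
  for (i in seq_along(species_specs)) {
    spec <- species_specs[[i]]
    locs <- sp$locations[[i]]
    for (k in seq_len(nrow(locs))) {
      tree_idx <- tree_idx + 1L
      tseed <- derive_seed(seed, 1000L + tree_idx)
      sk <- lsys_interpret(lsys_expand(spec$grammar, spec$iterations),
                           spec$params, seed = tseed, grammar = spec$grammar)
      tree <- assemble_tree(sk, spec$templates, seed = tseed,
                            radius_mean = spec$radius_mean,
                            radius_sd = spec$radius_sd,
                            species = spec$label,
                            location = c(locs$x[k], locs$y[k]))
      rows[[tree_idx]] <- tibble::tibble(
        x = locs$x[k], y = locs$y[k], species = spec$label, tree = list(tree))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(x = numeric(0), y = numeric(0), species = character(0),
                   tree = list())
  attr(out, "seed") <- seed
  attr(out, "min_spacing") <- min_spacing
  attr(out, "deleted") <- sp$deleted
  class(out) <- c("sim_forest", class(out))
  out
}

#' All leaf discs of a forest in field coordinates
#'
#' @param forest A `sim_forest`.
#' @return A `leaf_discs` tibble pooled over trees, with a `tree` index
#'   column.
#' @export
forest_leaf_discs <- function(forest) {
  stopifnot(inherits(forest, "sim_forest"))
  if (nrow(forest) == 0) {
    out <- empty_leaf_discs()
    out$tree <- integer(0)
    return(out)
  }
  discs <- lapply(seq_len(nrow(forest)), function(i) {
    d <- place_tree(forest$tree[[i]])
    d$tree <- i
    d
  })
  as_leaf_discs(dplyr::bind_rows(discs))
}

#' Write forest locations to CSV
#'
#' One row per tree: `x`, `y`, `species`, `seed`.
#'
#' @param forest A `sim_forest`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forest_csv <- function(forest, path) {
  df <- data.frame(x = forest$x, y = forest$y, species = forest$species,
                   seed = attr(forest, "seed"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an intensity mixture from YAML
#'
#' Expected keys: `domain` (x0, x1, y0, y1) and `components`, a list of maps
#' with `C`, `cx`, `cy`, `h`, `l`.
#'
#' @param path YAML file path.
#' @return An [intensity_mixture()].
#' @export
read_mixture_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  comps <- dplyr::bind_rows(lapply(cfg$components, tibble::as_tibble))
  intensity_mixture(comps, as.numeric(cfg$domain))
}
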