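#' Lindenmayer-system grammar
#'
#' An L-system is a parallel string-rewriting grammar defined by a set of
#' single-character variables, an axiom (initial string), a fixed alphabet of
#' special branching instructions `(`, `)`, `+`, `[`, and production rules
#' mapping variables to replacement strings. Expanding the grammar a few
#' iterations yields self-similar branching patterns which
#' [lsys_interpret()] turns into 3-D branch skeletons.
#'
#' Variables listed in `end_variables` denote starting/end branches (a leaf is
#' simplified as an end branch); their rendered form carries a trailing `)`
#' branch-end marker, so the token `"g)"` is rewritten atomically. This keeps
#' expanded strings consistent with the usual printed form of such grammars,
#' where a production like `g -> d(g)[g)+g)` produces
#' `d(d(g)[g)+g)[d(g)[g)+g)+d(g)[g)+g)` at the second iteration rather than
#' doubling the end markers.
#'
#' @param variables Character vector of single-character variable symbols.
#' @param axiom Nonempty string over the alphabet (variables plus specials).
#' @param rules Named list/character vector mapping variables to replacement
#'   strings over the alphabet.
#' @param end_variables Subset of `variables` treated as end branches whose
#'   trailing `)` is part of the rewritten token. Defaults to `"g"` when
#'   present.
#' @return An object of class `lsys_grammar`.
#' @examples
#' g <- lsys_grammar(c("g", "d"), "g", list(g = "d(g)[g)+g)"))
#' lsys_expand(g, 1)
#' @export
lsys_grammar <- function(variables, axiom, rules,
                         end_variables = intersect(variables, "g")) {
  variables <- as.character(variables)
  specials <- c("(", ")", "+", "[")
  if (any(nchar(variables) != 1L)) {
    stop("invalid grammar: variables must be single characters", call. = FALSE)
  }
  if (any(variables %in% specials)) {
    stop("invalid grammar: variables may not overlap the special symbols ( ) + [",
         call. = FALSE)
  }
  if (!is.character(axiom) || length(axiom) != 1L || nchar(axiom) == 0L) {
    stop("invalid grammar: axiom must be a nonempty string", call. = FALSE)
  }
  rules <- lapply(rules, as.character)
  if (length(rules) && (is.null(names(rules)) || any(names(rules) == ""))) {
    stop("invalid grammar: rules must be named by variable", call. = FALSE)
  }
  if (!all(names(rules) %in% variables)) {
    stop("invalid grammar: every production key must be a variable", call. = FALSE)
  }
  if (!all(end_variables %in% variables)) {
    stop("invalid grammar: end_variables must be variables", call. = FALSE)
  }
  alphabet <- c(variables, specials)
  check_string <- function(s, what) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(chars, alphabet)
    if (length(bad)) {
      stop(sprintf("invalid grammar: unknown symbol(s) %s in %s",
                   paste(sQuote(bad), collapse = ", "), what), call. = FALSE)
    }
  }
  check_string(axiom, "axiom")
  for (v in names(rules)) check_string(rules[[v]], sprintf("rule for '%s'", v))
  structure(
    list(variables = variables, axiom = axiom, rules = rules,
         specials = specials, end_variables = end_variables),
    class = "lsys_grammar"
  )
}

#' @export
print.lsys_grammar <- function(x, ...) {
  cat("<lsys_grammar>\n")
  cat("  variables:", paste(x$variables, collapse = " "), "\n")
  cat("  axiom:    ", x$axiom, "\n")
  for (v in names(x$rules)) cat(sprintf("  rule:      %s -> %s\n", v, x$rules[[v]]))
  invisible(x)
}

#' Canonical branching grammar
#'
#' The two-variable grammar with `g` an end branch, `d` a trunk/branch
#' segment, axiom `g` and production `g -> d(g)[g)+g)`: one iteration gives
#' the elementary branching pattern `d(g)[g)+g)`, further iterations nest it
#' self-similarly.
#'
#' @return An `lsys_grammar`.
#' @export
default_grammar <- function() {
  lsys_grammar(c("g", "d"), "g", list(g = "d(g)[g)+g)"))
}

# Tokenize a symbol string: a variable in `end_variables` immediately followed
# by ")" forms one atomic token ("g)"); every other character stands alone.
lsys_tokenize <- function(string, grammar) {
  chars <- strsplit(string, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% grammar$end_variables && i < n && chars[i + 1L] == ")") {
      tokens <- c(tokens, paste0(ch, ")"))
      i <- i + 2L
    } else if (ch %in% c(grammar$variables, grammar$specials)) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf("invalid grammar: unknown symbol '%s'", ch), call. = FALSE)
    }
  }
  tokens
}

#' Expand an L-system grammar
#'
#' Applies all production rules simultaneously (parallel rewriting)
#' `iterations` times to the axiom. Variables without a production and all
#' special symbols are copied unchanged. End-branch variables are rewritten
#' together with their trailing `)` marker as one token; if a production body
#' does not itself end in `)`, the marker is re-appended so branch ends are
#' preserved.
#'
#' @param grammar An [lsys_grammar()].
#' @param iterations Nonnegative number of rewriting passes; 0 returns the
#'   axiom.
#' @return The expanded symbol string.
#' @examples
#' lsys_expand(default_grammar(), 2)
#' @export
lsys_expand <- function(grammar, iterations) {
  stopifnot(inherits(grammar, "lsys_grammar"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L) {
    stop("iterations must be a nonnegative count", call. = FALSE)
  }
  tokens <- lsys_tokenize(grammar$axiom, grammar)
  rhs_tokens <- lapply(grammar$rules, lsys_tokenize, grammar = grammar)
  if (iterations > 0L) {
    for (iter in seq_len(iterations)) {
      out <- vector("list", length(tokens))
      for (k in seq_along(tokens)) {
        tok <- tokens[k]
        base <- sub("\\)$", "", tok)
        if (base %in% names(rhs_tokens)) {
          rep <- rhs_tokens[[base]]
          if (endsWith(tok, ")") && !endsWith(rep[length(rep)], ")")) {
            rep <- c(rep, ")")
          }
          out[[k]] <- rep
        } else {
          out[[k]] <- tok
        }
      }
      tokens <- unlist(out, use.names = FALSE)
    }
  }
  paste(tokens, collapse = "")
}

#' Geometry parameters for turtle interpretation
#'
#' Controls how a symbol string is mapped to a 3-D branch skeleton: the trunk
#' starts at the origin pointing along +z with `initial_length` (m) and
#' `initial_radius` (m); each child branch contracts length and radius by
#' `length_ratio` and `radius_ratio`, each perturbed per branch by Gaussian
#' noise (sd `ratio_noise_sd`, redrawn until the ratio stays in (0,1)); child
#' branches leave the parent axis at `branch_angle` radians plus Gaussian
#' noise (sd `angle_noise_sd`); mirrored (`+`) and trunk-advance (`[`)
#' branches attach at a point raised along the parent axis by a fraction of
#' the parent segment length drawn uniformly from `raise_fraction_range`,
#' avoiding perfectly symmetric structure. Azimuths of successive children
#' around the parent axis follow `azimuth_rule`: the golden angle
#' (about 137.5 degrees, phyllotaxis-like) or uniform random.
#'
#' @param initial_length,initial_radius Trunk length and radius in metres.
#' @param length_ratio,radius_ratio Contraction ratios in (0,1).
#' @param branch_angle Branching angle from the parent axis, radians.
#' @param ratio_noise_sd,angle_noise_sd Noise standard deviations
#'   (dimensionless / radians); 0 disables the noise.
#' @param raise_fraction_range Interval within (0,1); a degenerate interval
#'   `c(f, f)` makes the raise deterministic.
#' @param azimuth_rule `"golden-angle"` or `"uniform-random"`.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(initial_length = 1,
                            initial_radius = 0.05,
                            length_ratio = 0.7,
                            radius_ratio = 0.6,
                            branch_angle = 35 * pi / 180,
                            ratio_noise_sd = 0.05,
                            angle_noise_sd = 0.05,
                            raise_fraction_range = c(0.2, 0.5),
                            azimuth_rule = c("golden-angle", "uniform-random")) {
  azimuth_rule <- match.arg(azimuth_rule)
  stopifnot(
    initial_length > 0, initial_radius > 0,
    length_ratio > 0, length_ratio < 1,
    radius_ratio > 0, radius_ratio < 1,
    ratio_noise_sd >= 0, angle_noise_sd >= 0,
    length(raise_fraction_range) == 2,
    raise_fraction_range[1] > 0, raise_fraction_range[2] < 1,
    raise_fraction_range[1] <= raise_fraction_range[2]
  )
  structure(
    list(initial_length = initial_length, initial_radius = initial_radius,
         length_ratio = length_ratio, radius_ratio = radius_ratio,
         branch_angle = branch_angle,
         ratio_noise_sd = ratio_noise_sd, angle_noise_sd = angle_noise_sd,
         raise_fraction_range = raise_fraction_range,
         azimuth_rule = azimuth_rule),
    class = "geometry_params"
  )
}

# golden angle in radians
GOLDEN_ANGLE <- pi * (3 - sqrt(5))

# unit vector helper
vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) v / vnorm(v)
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal basis (u, v) perpendicular to unit vector h
perp_basis <- function(h) {
  ref <- if (abs(h[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- vunit(vcross(ref, h))
  v <- vcross(h, u)
  list(u = u, v = v)
}

#' Interpret a symbol string as a 3-D branch skeleton
#'
#' Turtle semantics: each variable token emits one branch segment along the
#' current heading; `(` opens a child branch at the current branch tip,
#' rotated off the parent axis by the branching angle at the next azimuth;
#' `)` (carried by end-branch tokens such as `g)`) closes the current branch
#' and returns to its parent; `+` opens a branch at the mirror azimuth of the
#' previous child, attached at a point raised along the parent axis by a
#' random fraction; `[` advances the attachment point up the parent axis
#' (growing the trunk) and opens a new branch there. Raising past the branch
#' tip extends the last emitted segment so the skeleton stays connected.
#'
#' @param symbols Symbol string (e.g. from [lsys_expand()]).
#' @param params A [geometry_params()] object.
#' @param seed Integer seed; the result is reproducible per seed, and
#'   seed-independent when all stochastic inputs are degenerate.
#' @param grammar Optional [lsys_grammar()] used for tokenization; by default
#'   any letter is a variable and a letter directly followed by `)` is an
#'   end-branch token.
#' @return A tibble of class `branch_skeleton`, one row per segment, with
#'   columns `x0,y0,z0,x1,y1,z1` (m), `radius_start`, `radius_end` (m),
#'   `depth` (0 = trunk) and `kind` (`"branch"` or `"end"`).
#' @examples
#' sk <- lsys_interpret(lsys_expand(default_grammar(), 3), geometry_params(), seed = 1)
#' nrow(sk)
#' @export
lsys_interpret <- function(symbols, params = geometry_params(), seed = 1L,
                           grammar = NULL) {
  stopifnot(inherits(params, "geometry_params"))
  if (!is.character(symbols) || length(symbols) != 1L || nchar(symbols) == 0L) {
    stop("symbols must be a nonempty string", call. = FALSE)
  }
  if (is.null(grammar)) {
    letters_used <- unique(grep("[A-Za-z]", strsplit(symbols, "")[[1]], value = TRUE))
    if (length(letters_used) == 0L) {
      stop("symbols contains no variable tokens", call. = FALSE)
    }
    grammar <- lsys_grammar(letters_used, symbols, list(),
                            end_variables = letters_used)
  }
  tokens <- lsys_tokenize(symbols, grammar)

  withr::with_seed(as.integer(seed), {
    draw_ratio <- function(base, sd) {
      if (sd <= 0) return(base)
      for (i in 1:100) {
        r <- base + stats::rnorm(1, 0, sd)
        if (r > 0 && r < 1) return(r)
      }
      min(max(base, 1e-6), 1 - 1e-6)
    }
    draw_angle <- function(base, sd) {
      if (sd <= 0) base else base + stats::rnorm(1, 0, sd)
    }
    draw_raise <- function(rng) {
      if (rng[1] == rng[2]) rng[1] else stats::runif(1, rng[1], rng[2])
    }

    segments <- list()
    state <- list(
      pos = c(0, 0, 0), heading = c(0, 0, 1),
      len = params$initial_length, rad = params$initial_radius,
      depth = 0L, azimuth_index = 0L,
      last_child_az = NA_real_, last_child_attach = NULL,
      last_seg = NA_integer_
    )
    stack <- list()

    next_azimuth <- function(st) {
      if (params$azimuth_rule == "golden-angle") {
        st$azimuth_index * GOLDEN_ANGLE
      } else {
        stats::runif(1, 0, 2 * pi)
      }
    }

    child_of <- function(st, azimuth, attach) {
      lr <- draw_ratio(params$length_ratio, params$ratio_noise_sd)
      rr <- draw_ratio(params$radius_ratio, params$ratio_noise_sd)
      ang <- draw_angle(params$branch_angle, params$angle_noise_sd)
      b <- perp_basis(st$heading)
      dir <- cos(ang) * st$heading +
        sin(ang) * (cos(azimuth) * b$u + sin(azimuth) * b$v)
      list(pos = attach, heading = vunit(dir),
           len = st$len * lr, rad = st$rad * rr,
           depth = st$depth + 1L, azimuth_index = 0L,
           last_child_az = NA_real_, last_child_attach = NULL,
           last_seg = NA_integer_)
    }

    open_branch <- function(azimuth, attach) {
      state$last_child_az <<- azimuth
      state$last_child_attach <<- attach
      stack[[length(stack) + 1L]] <<- state
      state <<- child_of(state, azimuth, attach)
    }

    # raise the current branch tip by frac * segment length along the heading,
    # extending the last emitted segment so the attachment stays on the skeleton
    raise_tip <- function(frac) {
      delta <- frac * state$len
      new_tip <- state$pos + delta * state$heading
      if (!is.na(state$last_seg)) {
        seg <- segments[[state$last_seg]]
        seg$x1 <- new_tip[1]; seg$y1 <- new_tip[2]; seg$z1 <- new_tip[3]
        segments[[state$last_seg]] <<- seg
      }
      state$pos <<- new_tip
      new_tip
    }

    for (tok in tokens) {
      is_end <- endsWith(tok, ")") && nchar(tok) == 2L
      base <- sub("\\)$", "", tok)
      if (base %in% grammar$variables) {
        tip <- state$pos + state$len * state$heading
        segments[[length(segments) + 1L]] <- list(
          x0 = state$pos[1], y0 = state$pos[2], z0 = state$pos[3],
          x1 = tip[1], y1 = tip[2], z1 = tip[3],
          radius_start = state$rad,
          radius_end = state$rad * params$radius_ratio,
          depth = state$depth,
          kind = if (is_end || base %in% grammar$end_variables) "end" else "branch"
        )
        state$pos <- tip
        state$last_seg <- length(segments)
        if (is_end) {
          if (length(stack) == 0L) {
            stop("malformed string: branch end with no open branch", call. = FALSE)
          }
          state <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
        }
      } else if (tok == "(") {
        state$azimuth_index <- state$azimuth_index + 1L
        open_branch(next_azimuth(state), state$pos)
      } else if (tok == "[") {
        attach <- raise_tip(draw_raise(params$raise_fraction_range))
        state$azimuth_index <- state$azimuth_index + 1L
        open_branch(next_azimuth(state), attach)
      } else if (tok == "+") {
        az <- if (is.na(state$last_child_az)) {
          state$azimuth_index <- state$azimuth_index + 1L
          next_azimuth(state)
        } else {
          state$last_child_az + pi
        }
        attach <- raise_tip(draw_raise(params$raise_fraction_range))
        open_branch(az, attach)
      } else if (tok == ")") {
        if (length(stack) == 0L) {
          stop("malformed string: branch end with no open branch", call. = FALSE)
        }
        state <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
      } else {
        stop(sprintf("unknown token '%s'", tok), call. = FALSE)
      }
    }

    out <- dplyr::bind_rows(lapply(segments, tibble::as_tibble))
    attr(out, "root") <- c(0, 0, 0)
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("branch_skeleton", class(out))
    out
  })
}

#' Write a branch skeleton to CSV
#'
#' One segment per row: start/end coordinates, radii, depth and kind.
#'
#' @param skeleton A `branch_skeleton` tibble from [lsys_interpret()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_skeleton_csv <- function(skeleton, path) {
  utils::write.csv(as.data.frame(skeleton), path, row.names = FALSE)
  invisible(path)
}

#' Read grammar and geometry configuration from YAML
#'
#' Expected keys: `variables`, `axiom`, `rules` (a map), optional
#' `geometry.*` entries matching [geometry_params()] arguments, optional
#' `seed`.
#'
#' @param path YAML file path.
#' @return A list with elements `grammar`, `params` and `seed`.
#' @export
read_tree_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  grammar <- lsys_grammar(cfg$variables, cfg$axiom, cfg$rules)
  geo <- cfg$geometry %||% list()
  if (!is.null(geo$raise_fraction_range)) {
    geo$raise_fraction_range <- as.numeric(geo$raise_fraction_range)
  }
  params <- do.call(geometry_params, geo)
  list(grammar = grammar, params = params, seed = cfg$seed %||% 1L)
}
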