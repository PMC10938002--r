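# Dot-array stimulus construction: area-matched adapter and test arrays,
# rejection-sampled non-overlapping positions, rendering, and trial designs.

#' Stimulus specification for the adaptation paradigm
#'
#' Bundles the geometric and luminance-matching parameters of the dot-array
#' stimuli: five test numerosities sharing a fixed total bright area, two
#' adapter arrays (10 vs 160 dots) matched to a larger common area, a circular
#' presentation field, a minimum edge-to-edge dot gap and a fixation exclusion
#' zone.
#'
#' All lengths are degrees of visual angle, areas deg^2, luminance cd/m^2.
#'
#' Note that the printed default geometry is *infeasible for placement*: the
#' adapter area (181 deg^2) exceeds the area of an 11-deg-diameter field
#' (~95 deg^2), and even the test arrays (80.4 deg^2, i.e. 85% fill) cannot
#' satisfy the 0.25-deg gap constraint in that field. Array constructors
#' therefore fail with a packing-infeasible error under the defaults; pass a
#' larger `field_diameter` (the pipeline uses 30 deg) to actually generate
#' arrays. The analytic relations (diameters, areas) are unaffected.
#'
#' @param test_numerosities Integer vector of test numerosities, ascending.
#' @param test_total_area Common total dot area of every test array (deg^2).
#' @param adapter_total_area Common total dot area of both adapters (deg^2).
#' @param adapter_high_n,adapter_low_n Dot counts of the two adapters.
#' @param background_luminance Background luminance (cd/m^2).
#' @param dot_luminance Dot (white) level used when rendering (cd/m^2).
#' @param field_diameter Diameter of the virtual circular field (deg).
#' @param min_gap Minimum edge-to-edge distance between dots (deg).
#' @param fixation_radius Radius of the fixation exclusion disc (deg).
#' @param jitter_fraction Heterogeneous-size condition: total fractional range
#'   of dot diameters around the homogeneous value (0.5 means +/-25%).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(test_numerosities = c(10L, 14L, 20L, 28L, 40L),
                          test_total_area = 80.4,
                          adapter_total_area = 181,
                          adapter_high_n = 160L,
                          adapter_low_n = 10L,
                          background_luminance = 129,
                          dot_luminance = 220,
                          field_diameter = 11,
                          min_gap = 0.25,
                          fixation_radius = 0.4,
                          jitter_fraction = 0.5) {
  stopifnot(
    length(test_numerosities) >= 1, all(test_numerosities >= 1),
    !is.unsorted(test_numerosities, strictly = TRUE),
    test_total_area > 0, adapter_total_area > 0,
    adapter_high_n >= 1, adapter_low_n >= 1,
    field_diameter > 0, min_gap >= 0, fixation_radius >= 0,
    jitter_fraction >= 0, jitter_fraction < 2
  )
  structure(list(
    test_numerosities = as.integer(test_numerosities),
    test_total_area = test_total_area,
    adapter_total_area = adapter_total_area,
    adapter_high_n = as.integer(adapter_high_n),
    adapter_low_n = as.integer(adapter_low_n),
    background_luminance = background_luminance,
    dot_luminance = dot_luminance,
    field_diameter = field_diameter,
    min_gap = min_gap,
    fixation_radius = fixation_radius,
    jitter_fraction = jitter_fraction
  ), class = "stimulus_spec")
}

#' Diameter giving a fixed total area for n equal dots
#'
#' Solves `n * pi * (d/2)^2 == total_area` for `d`. This is the rule that
#' keeps total bright area (hence mean display luminance) constant across
#' numerosities: 160 adapter dots come out at 1.2 deg, 10 at 4.8 deg; the test
#' series 10/14/20/28/40 at 80.4 deg^2 gives 3.2/2.7/2.3/1.9/1.6 deg.
#'
#' @param n Number of dots (vectorized).
#' @param total_area Total dot area (deg^2).
#' @return Dot diameter(s) in deg.
#' @export
equal_area_diameter <- function(n, total_area) {
  if (any(!is.finite(n)) || any(n < 1))
    stop("invalid-parameter: n must be >= 1", call. = FALSE)
  if (any(!is.finite(total_area)) || any(total_area <= 0))
    stop("invalid-parameter: total_area must be > 0", call. = FALSE)
  2 * sqrt(total_area / (n * pi))
}

#' Construct a dot-array object
#'
#' @param centers Two-column matrix of dot centers (x, y) in deg, origin at
#'   fixation, x rightward, y upward.
#' @param diameters Numeric vector of dot diameters (deg), one per dot.
#' @param role One of `"adapter-high"`, `"adapter-low"`, `"test"`.
#' @param experiment 1 (homogeneous dot size) or 2 (heterogeneous).
#' @param field_diameter Field diameter the array was generated for (deg).
#' @return Object of class `dot_array`.
#' @export
dot_array <- function(centers, diameters, role = "test", experiment = 1L,
                      field_diameter = 11) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  diameters <- as.numeric(diameters)
  stopifnot(nrow(centers) == length(diameters))
  structure(list(
    centers = centers,
    diameters = diameters,
    numerosity = length(diameters),
    role = match.arg(role, c("adapter-high", "adapter-low", "test")),
    experiment = as.integer(experiment),
    field_diameter = field_diameter
  ), class = "dot_array")
}

#' Check the geometric invariants of a dot array
#'
#' Asserts that every dot lies entirely within the field, that all pairwise
#' edge-to-edge gaps meet `min_gap`, and that no dot overlaps the fixation
#' exclusion disc.
#'
#' @param array A `dot_array`.
#' @param min_gap Minimum edge-to-edge gap (deg).
#' @param fixation_radius Fixation exclusion disc radius (deg).
#' @return `TRUE` invisibly; stops with a descriptive error otherwise.
#' @export
validate_dot_array <- function(array, min_gap = 0.25, fixation_radius = 0.4) {
  r <- array$diameters / 2
  if (array$numerosity != length(r) || array$numerosity != nrow(array$centers))
    stop("dot_array: centers/diameters/numerosity mismatch", call. = FALSE)
  if (array$numerosity == 0L) return(invisible(TRUE))
  d0 <- sqrt(rowSums(array$centers^2))
  if (any(d0 + r > array$field_diameter / 2 + 1e-9))
    stop("dot_array: dot extends beyond the field", call. = FALSE)
  if (any(d0 - r < fixation_radius - 1e-9))
    stop("dot_array: dot overlaps the fixation exclusion zone", call. = FALSE)
  if (array$numerosity > 1L) {
    dd <- as.matrix(stats::dist(array$centers))
    gap <- dd - outer(r, r, "+")
    diag(gap) <- Inf
    if (any(gap < min_gap - 1e-9))
      stop("dot_array: pairwise gap below minimum", call. = FALSE)
  }
  invisible(TRUE)
}

#' Total bright surface area of an array
#'
#' @param array A `dot_array` (or a numeric vector of diameters).
#' @return Total dot area in deg^2 (0 for an empty array).
#' @export
total_area <- function(array) {
  d <- if (inherits(array, "dot_array")) array$diameters else as.numeric(array)
  if (length(d) == 0L) return(0)
  sum(pi * (d / 2)^2)
}

# Seed the RNG for the duration of the calling function, restoring the
# caller's stream on exit. No-op when seed is NULL.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }
  do.call(on.exit, list(as.call(list(restore)), add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Sample non-overlapping dot positions by rejection
#'
#' Places `n` dots one by one with uniform center proposals in the admissible
#' annulus (inside the field, outside the fixation exclusion zone), rejecting
#' proposals that violate the minimum gap against already-placed dots. Dots
#' are placed in decreasing size order (positions are returned in the input
#' order). After `max_attempts` failed proposals for one dot the whole array
#' restarts; after `max_restarts` restarts a packing-infeasible error names
#' the constraint that dominated the failures.
#'
#' @param n Number of dots.
#' @param diameters Diameter of each dot (recycled to length `n`).
#' @param field_diameter,min_gap,fixation_radius Geometry, in deg.
#' @param seed Optional integer seed; identical seed implies identical output.
#' @param max_attempts Failed proposals tolerated per dot before a restart.
#' @param max_restarts Restarts tolerated before giving up.
#' @return `n` x 2 matrix of centers (deg).
#' @export
sample_positions <- function(n, diameters, field_diameter = 11,
                             min_gap = 0.25, fixation_radius = 0.4,
                             seed = NULL, max_attempts = 10000,
                             max_restarts = 100) {
  stopifnot(n >= 1, field_diameter > 0)
  diameters <- rep_len(as.numeric(diameters), n)
  r <- diameters / 2
  rmax <- field_diameter / 2 - r       # stay fully inside the field
  rmin <- fixation_radius + r          # stay clear of fixation
  bad <- which(rmax < rmin - 1e-12 | rmax < 0)
  if (length(bad))
    stop(sprintf(paste0("packing-infeasible: dot of diameter %.3g deg has no ",
                        "admissible center (field %.3g deg, fixation radius %.3g deg)"),
                 diameters[bad[1]], field_diameter, fixation_radius),
         call. = FALSE)
  if (total_area(diameters) > pi * (field_diameter / 2)^2)
    stop(sprintf(paste0("packing-infeasible: total dot area %.4g deg^2 exceeds ",
                        "field area %.4g deg^2"),
                 total_area(diameters), pi * (field_diameter / 2)^2),
         call. = FALSE)
  local_seed(seed)
  ord <- order(r, decreasing = TRUE)   # large dots first: much easier packing
  rs <- r[ord]
  for (restart in seq_len(max_restarts)) {
    xy <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        rad <- sqrt(stats::runif(1, rmin[ord[i]]^2, rmax[ord[i]]^2))
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(rad * cos(th), rad * sin(th))
        if (i > 1L) {
          dd <- sqrt((xy[seq_len(i - 1L), 1] - p[1])^2 +
                     (xy[seq_len(i - 1L), 2] - p[2])^2)
          if (any(dd < rs[seq_len(i - 1L)] + rs[i] + min_gap)) next
        }
        xy[i, ] <- p
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      out <- matrix(NA_real_, n, 2)
      out[ord, ] <- xy
      return(out)
    }
  }
  stop(sprintf(paste0("packing-infeasible: minimum-gap constraint (%.3g deg) could ",
                      "not be satisfied for %d dots in a %.3g-deg field after %d restarts"),
               min_gap, n, field_diameter, max_restarts), call. = FALSE)
}

#' Construct an adapter array
#'
#' Adapter arrays contain 160 ("high") or 10 ("low") equal dots whose common
#' diameter is chosen so that both share the spec's adapter total area,
#' equating luminance between the two adaptation conditions.
#'
#' @param condition `"high"` or `"low"`.
#' @param spec A [stimulus_spec()].
#' @param seed Optional integer seed for dot placement.
#' @return A `dot_array`.
#' @export
make_adapter <- function(condition = c("high", "low"), spec = stimulus_spec(),
                         seed = NULL) {
  condition <- match.arg(condition)
  n <- if (condition == "high") spec$adapter_high_n else spec$adapter_low_n
  d <- equal_area_diameter(n, spec$adapter_total_area)
  xy <- sample_positions(n, rep(d, n), spec$field_diameter, spec$min_gap,
                         spec$fixation_radius, seed = seed)
  dot_array(xy, rep(d, n), role = paste0("adapter-", condition),
            experiment = NA_integer_, field_diameter = spec$field_diameter)
}

#' Construct a test array
#'
#' Experiment 1 uses homogeneous dot sizes: all dots take the equal-area
#' diameter for that numerosity, so every test array has exactly the spec's
#' test total area. Experiment 2 draws each diameter uniformly over a range
#' spanning `jitter_fraction` of the homogeneous diameter (default +/-25%),
#' which preserves the mean diameter per numerosity but lets total area vary
#' slightly from array to array.
#'
#' @param n Test numerosity; must belong to `spec$test_numerosities`.
#' @param experiment 1 or 2.
#' @param spec A [stimulus_spec()].
#' @param seed Optional integer seed (drives both diameters and positions).
#' @return A `dot_array`.
#' @export
make_test <- function(n, experiment = 1L, spec = stimulus_spec(), seed = NULL) {
  n <- as.integer(n)
  if (!n %in% spec$test_numerosities)
    stop(sprintf("invalid-parameter: numerosity %d not in {%s}", n,
                 paste(spec$test_numerosities, collapse = ", ")), call. = FALSE)
  if (!experiment %in% c(1L, 2L))
    stop("invalid-parameter: experiment must be 1 or 2", call. = FALSE)
  d0 <- equal_area_diameter(n, spec$test_total_area)
  local_seed(seed)
  diameters <- if (experiment == 1L) rep(d0, n)
  else stats::runif(n, d0 * (1 - spec$jitter_fraction / 2),
                    d0 * (1 + spec$jitter_fraction / 2))
  xy <- sample_positions(n, diameters, spec$field_diameter, spec$min_gap,
                         spec$fixation_radius, seed = NULL)
  dot_array(xy, diameters, role = "test", experiment = experiment,
            field_diameter = spec$field_diameter)
}

#' Render a dot array to a luminance raster
#'
#' Converts degrees to pixels at `pixels_per_degree` and paints each dot by
#' center-distance <= radius membership on a square raster covering the field.
#' Bright-pixel count divided by `pixels_per_degree^2` approximates the
#' array's analytic total area.
#'
#' @param array A `dot_array`.
#' @param pixels_per_degree Raster resolution (> 0).
#' @param background_level,dot_level Luminance values written to background
#'   and dot pixels (any units; defaults mirror the display: gray 129,
#'   white 220 cd/m^2).
#' @return Numeric matrix (rows = y, columns = x), class `pupil_raster`.
#' @export
render_array <- function(array, pixels_per_degree, background_level = 129,
                         dot_level = 220) {
  if (!is.finite(pixels_per_degree) || pixels_per_degree <= 0)
    stop("invalid-parameter: pixels_per_degree must be > 0", call. = FALSE)
  side <- ceiling(array$field_diameter * pixels_per_degree)
  img <- matrix(background_level, side, side)
  if (array$numerosity > 0L) {
    # pixel-center coordinates in deg, origin at the field center
    px <- ((seq_len(side)) - 0.5) / pixels_per_degree - array$field_diameter / 2
    for (i in seq_len(array$numerosity)) {
      cx <- array$centers[i, 1]; cy <- array$centers[i, 2]
      r <- array$diameters[i] / 2
      xi <- which(abs(px - cx) <= r)
      yi <- which(abs(px - cy) <= r)
      if (!length(xi) || !length(yi)) next
      sub <- outer(px[yi] - cy, px[xi] - cx,
                   function(dy, dx) dx * dx + dy * dy) <= r * r
      block <- img[yi, xi, drop = FALSE]
      block[sub] <- dot_level
      img[yi, xi] <- block
    }
  }
  structure(img, class = c("pupil_raster", "matrix"),
            pixels_per_degree = pixels_per_degree,
            background_level = background_level, dot_level = dot_level)
}

#' Build a full trial design
#'
#' Each participant runs 4 sessions, 2 per adaptation condition (session
#' order randomized), and each session presents every test numerosity
#' `reps_per_numerosity_per_session` times in shuffled order. With the
#' default 18 repetitions this yields 4 x 5 x 18 = 360 trials per
#' participant.
#'
#' @param participants Character or integer vector of participant ids.
#' @param experiment 1 or 2 (recycled across participants if length 1).
#' @param reps_per_numerosity_per_session Repetitions of each numerosity in
#'   one session (>= 1).
#' @param spec A [stimulus_spec()].
#' @param seed Optional integer seed controlling condition order and shuffling.
#' @return `data.frame` with columns participant_id, experiment, session,
#'   condition, trial, numerosity.
#' @export
build_design <- function(participants, experiment = 1L,
                         reps_per_numerosity_per_session = 18L,
                         spec = stimulus_spec(), seed = NULL) {
  stopifnot(length(participants) >= 1, reps_per_numerosity_per_session >= 1)
  experiment <- rep_len(as.integer(experiment), length(participants))
  local_seed(seed)
  reps <- as.integer(reps_per_numerosity_per_session)
  out <- vector("list", length(participants))
  for (p in seq_along(participants)) {
    conds <- sample(c("high", "high", "low", "low"))
    sess <- vector("list", 4L)
    for (s in 1:4) {
      nums <- sample(rep(spec$test_numerosities, reps))
      sess[[s]] <- data.frame(
        participant_id = participants[p],
        experiment = experiment[p],
        session = s,
        condition = conds[s],
        trial = seq_along(nums),
        numerosity = nums,
        stringsAsFactors = FALSE
      )
    }
    out[[p]] <- do.call(rbind, sess)
  }
  design <- do.call(rbind, out)
  rownames(design) <- NULL
  design
}

#' @export
print.dot_array <- function(x, ...) {
  cat(sprintf("<dot_array> %s: %d dots, total area %.2f deg^2, field %.3g deg\n",
              x$role, x$numerosity, total_area(x), x$field_diameter))
  invisible(x)
}

#' Serialize a dot array to JSON / read it back
#'
#' @param array A `dot_array`.
#' @param path File path.
#' @return `write_array_json` returns `path` invisibly; `read_array_json`
#'   returns a `dot_array`.
#' @export
write_array_json <- function(array, path) {
  jsonlite::write_json(list(
    centers = unname(array$centers), diameters = array$diameters,
    numerosity = array$numerosity, role = array$role,
    experiment = array$experiment, field_diameter = array$field_diameter
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_array_json
#' @export
read_array_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dot_array(x$centers, x$diameters, role = x$role,
            experiment = if (is.null(x$experiment) || is.na(x$experiment)) NA_integer_ else x$experiment,
            field_diameter = x$field_diameter)
}

#' Write / read a trial design as a tab-separated table
#'
#' @param design Data frame from [build_design()].
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` a data frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
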