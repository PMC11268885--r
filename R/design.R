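#' Ring grid of nominal feature values
#'
#' Nine values 0, 40, ..., 320 degrees: the fixed set from which both item
#' locations and item colors are drawn.
#' @return Numeric vector of 9 grid values in degrees.
#' @export
ring_grid <- function() seq(0, 320, by = 40)

#' Generate ring-valued trial designs
#'
#' Builds a sequence of three-item trials. Each trial carries three locations
#' and three colors drawn from the 9-point ring grid (values 0-320 degrees in
#' 40-degree steps) under the task constraints: within-trial locations are
#' pairwise distinct (hence at least 40 degrees apart at the nominal grid),
#' within-trial colors are pairwise distinct, and for every serial position
#' the color value differs from the location value. In the aligned-trajectory
#' (AT) condition the color triple is the location triple rotated by a random
#' nonzero grid angle, so the signed inter-item distances d12 and d23 match
#' exactly across domains; in the misaligned (MAT) condition color triples are
#' resampled until the full-trajectory match fails (a single matching leg is
#' permitted). Conditions are randomly interleaved. A small uniform jitter
#' with random sign is added to each nominal value after constraint checking.
#'
#' @param n_trials Number of trials (default 648, the full two-session design).
#' @param at_fraction Proportion of aligned-trajectory trials (default 0.5).
#' @param jitter_range Length-2 vector, degrees: jitter magnitude drawn
#'   uniformly from this range, sign random. Must lie within [0, 20).
#' @param n_blocks Number of equal-size contiguous recording blocks whose ids
#'   are carried to the leave-one-block-out decoder (default 8).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A data.frame with one row per trial: `trial`, `condition`
#'   ("AT"/"MAT"), `block`, nominal grid values `loc1_nom`..`loc3_nom`,
#'   `col1_nom`..`col3_nom`, and jittered presented values `loc1`..`col3`.
#' @export
generate_design <- function(n_trials = 648, at_fraction = 0.5,
                            jitter_range = c(1, 3), n_blocks = 8,
                            seed = 1) {
  stopifnot(n_trials >= 1, at_fraction >= 0, at_fraction <= 1,
            length(jitter_range) == 2, n_blocks >= 1)
  if (any(jitter_range < 0) || any(jitter_range >= 20) ||
      jitter_range[1] > jitter_range[2])
    stop("jitter_range must be an increasing pair within [0, 20) degrees; ",
         "larger jitter would break the 40-degree grid spacing")
  set.seed(seed)
  grid <- ring_grid()
  n_at <- round(n_trials * at_fraction)
  condition <- sample(rep(c("AT", "MAT"), c(n_at, n_trials - n_at)))

  loc <- matrix(NA_real_, n_trials, 3)
  col <- matrix(NA_real_, n_trials, 3)
  for (i in seq_len(n_trials)) {
    li <- sample(grid, 3)
    if (condition[i] == "AT") {
      rot <- sample(grid[-1], 1)  # nonzero rotation keeps color != location
      ci <- wrap360(li + rot)
    } else {
      repeat {
        ci <- sample(grid, 3)
        if (any(ci == li)) next                 # color == location at a position
        if (!isTRUE(is_aligned(li, ci))) break  # full-trajectory match must fail
      }
    }
    loc[i, ] <- li
    col[i, ] <- ci
  }

  jit <- function(n) {
    mag <- runif(n, jitter_range[1], jitter_range[2])
    mag * sample(c(-1, 1), n, replace = TRUE)
  }
  loc_j <- wrap360(loc + matrix(jit(3 * n_trials), n_trials, 3))
  col_j <- wrap360(col + matrix(jit(3 * n_trials), n_trials, 3))

  block <- rep(seq_len(n_blocks), each = ceiling(n_trials / n_blocks),
               length.out = n_trials)

  out <- data.frame(
    trial = seq_len(n_trials), condition = condition, block = block,
    loc1_nom = loc[, 1], loc2_nom = loc[, 2], loc3_nom = loc[, 3],
    col1_nom = col[, 1], col2_nom = col[, 2], col3_nom = col[, 3],
    loc1 = loc_j[, 1], loc2 = loc_j[, 2], loc3 = loc_j[, 3],
    col1 = col_j[, 1], col2 = col_j[, 2], col3 = col_j[, 3],
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- seed
  attr(out, "jitter_range") <- jitter_range
  out
}

#' Aligned-trajectory predicate
#'
#' TRUE when both the first-to-second and second-to-third signed circular
#' distances match between two value triples.
#' @param a,b Numeric length-3 vectors of ring values in degrees.
#' @return Logical.
#' @export
is_aligned <- function(a, b) {
  circ_diff(a[2], a[1]) == circ_diff(b[2], b[1]) &&
    circ_diff(a[3], a[2]) == circ_diff(b[3], b[2])
}

#' Check design constraints
#'
#' Counts violations of the generator's invariants on a design table:
#' within-trial distinctness (>= 40 degrees on the nominal grid) for locations
#' and for colors, color != location at each serial position, AT trials with
#' matched trajectories, MAT trials with an unmatched full trajectory.
#'
#' @param design A design data.frame from [generate_design()].
#' @return Named integer vector of violation counts (all zero for a valid
#'   design).
#' @export
validate_design <- function(design) {
  locs <- as.matrix(design[, c("loc1_nom", "loc2_nom", "loc3_nom")])
  cols <- as.matrix(design[, c("col1_nom", "col2_nom", "col3_nom")])
  min_sep <- function(m) apply(m, 1, function(v)
    min(abs(wrap180(c(v[1] - v[2], v[1] - v[3], v[2] - v[3])))))
  aligned <- vapply(seq_len(nrow(design)),
                    function(i) is_aligned(locs[i, ], cols[i, ]), logical(1))
  c(
    loc_spacing   = sum(min_sep(locs) < 40),
    col_spacing   = sum(min_sep(cols) < 40),
    col_eq_loc    = sum(rowSums(cols == locs) > 0),
    at_misaligned = sum(design$condition == "AT" & !aligned),
    mat_aligned   = sum(design$condition == "MAT" & aligned)
  )
}

#' Simulate behavioral reports
#'
#' Draws reported locations and colors around the presented (jittered) values
#' with von Mises circular noise. When `coupling_sd > 0`, aligned-trajectory
#' (AT) trials additionally receive a shared trajectory perturbation: one
#' normal draw per leg (1-2 and 2-3) is added to the second item's error (leg
#' 1-2) and to the third item's error (legs 1-2 plus 2-3) in *both* domains,
#' so the location and color trajectory errors of AT trials co-vary while
#' per-item noise stays independent. MAT trials never receive coupling.
#'
#' @param design Design table from [generate_design()].
#' @param kappa_location,kappa_color Von Mises concentrations of per-item
#'   report noise (> 0). Larger kappa = more precise memory; location memory
#'   is more precise than color in this task, hence the asymmetric defaults.
#' @param coupling_sd SD (degrees) of the shared AT trajectory perturbation;
#'   0 disables coupling.
#' @param seed Integer seed.
#' @return data.frame aligned to `design` rows: `trial`, `condition`, reported
#'   `loc1`..`loc3`, `col1`..`col3` in [0, 360).
#' @export
simulate_behavior <- function(design, kappa_location = 12, kappa_color = 6,
                              coupling_sd = 8, seed = 1) {
  stopifnot(kappa_location > 0, kappa_color > 0, coupling_sd >= 0)
  set.seed(seed)
  n <- nrow(design)
  loc_true <- as.matrix(design[, c("loc1", "loc2", "loc3")])
  col_true <- as.matrix(design[, c("col1", "col2", "col3")])

  e_loc <- matrix(wrap180(rvonmises(3 * n, 0, kappa_location)), n, 3)
  e_col <- matrix(wrap180(rvonmises(3 * n, 0, kappa_color)), n, 3)

  if (coupling_sd > 0) {
    at <- design$condition == "AT"
    g12 <- rnorm(n, 0, coupling_sd)
    g23 <- rnorm(n, 0, coupling_sd)
    e_loc[at, 2] <- e_loc[at, 2] + g12[at]
    e_col[at, 2] <- e_col[at, 2] + g12[at]
    e_loc[at, 3] <- e_loc[at, 3] + g12[at] + g23[at]
    e_col[at, 3] <- e_col[at, 3] + g12[at] + g23[at]
  }

  rep_loc <- wrap360(loc_true + e_loc)
  rep_col <- wrap360(col_true + e_col)
  data.frame(
    trial = design$trial, condition = design$condition,
    loc1 = rep_loc[, 1], loc2 = rep_loc[, 2], loc3 = rep_loc[, 3],
    col1 = rep_col[, 1], col2 = rep_col[, 2], col3 = rep_col[, 3],
    stringsAsFactors = FALSE
  )
}
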