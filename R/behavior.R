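#' Per-trial response errors
#'
#' Signed circular difference between the reported and the true (presented)
#' value, per trial, domain and serial position, in long format.
#'
#' @param design Design table ([generate_design()]): truth.
#' @param reports Report table ([simulate_behavior()] or user data) with the
#'   same trial ordering and columns `loc1..loc3`, `col1..col3` in degrees.
#' @return data.frame with columns `trial`, `condition`, `domain`
#'   ("location"/"color"), `position` (1-3), `error` in (-180, 180].
#' @export
response_errors <- function(design, reports) {
  stopifnot(nrow(design) == nrow(reports),
            all(design$trial == reports$trial))
  out <- expand.grid(position = 1:3, trial = design$trial,
                     domain = c("location", "color"),
                     stringsAsFactors = FALSE)
  out <- out[, c("trial", "domain", "position")]
  pick <- function(df, dm, p) df[[paste0(substr(dm, 1, 3), p)]]
  err <- mapply(function(dm, p, i) {
    circ_diff(pick(reports, dm, p)[i], pick(design, dm, p)[i])
  }, out$domain, out$position, match(out$trial, design$trial))
  out$condition <- design$condition[match(out$trial, design$trial)]
  out$error <- as.numeric(err)
  out[, c("trial", "condition", "domain", "position", "error")]
}

#' Trajectory error for one leg
#'
#' Wrapped circular difference of two item errors, later minus earlier: the
#' error of the reported inter-item trajectory relative to the true one. A
#' shared (common-rotation) error on both items cancels.
#'
#' @param e_earlier,e_later Item response errors in degrees.
#' @return Signed trajectory error in (-180, 180].
#' @export
trajectory_error <- function(e_earlier, e_later) wrap180(e_later - e_earlier)

#' Trajectory-error table
#'
#' Expands a long error table ([response_errors()]) into per-trial, per-domain
#' trajectory errors for the three legs 1-2, 2-3 and 1-3.
#'
#' @param errors Long error table from [response_errors()].
#' @return data.frame with `trial`, `condition`, `domain`, `leg`
#'   ("12"/"23"/"13"), `error` in (-180, 180].
#' @export
trajectory_errors <- function(errors) {
  wide <- stats::reshape(errors, idvar = c("trial", "condition", "domain"),
                         timevar = "position", direction = "wide")
  legs <- list(`12` = c(1, 2), `23` = c(2, 3), `13` = c(1, 3))
  out <- do.call(rbind, lapply(names(legs), function(lg) {
    e1 <- wide[[paste0("error.", legs[[lg]][1])]]
    e2 <- wide[[paste0("error.", legs[[lg]][2])]]
    data.frame(trial = wide$trial, condition = wide$condition,
               domain = wide$domain, leg = lg,
               error = trajectory_error(e1, e2), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Memory-precision summary
#'
#' Precision (1/sigma, sigma the circular SD of response error in radians) per
#' domain x condition x serial position, and collapsed over positions.
#'
#' @param errors Long error table from [response_errors()].
#' @return data.frame with `domain`, `condition`, `position` ("all" or 1-3),
#'   `sigma` (radians) and `precision` (1/radians).
#' @export
precision_summary <- function(errors) {
  cells <- rbind(
    expand.grid(domain = c("location", "color"), condition = c("AT", "MAT"),
                position = "all", stringsAsFactors = FALSE),
    expand.grid(domain = c("location", "color"), condition = c("AT", "MAT"),
                position = as.character(1:3), stringsAsFactors = FALSE)
  )
  cells$sigma <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- errors$domain == cells$domain[i] &
      errors$condition == cells$condition[i] &
      (cells$position[i] == "all" | errors$position == cells$position[i])
    circular_sd(errors$error[sel])
  }, numeric(1))
  cells$precision <- 1 / cells$sigma
  cells
}

#' Within-subject circular correlation of trajectory errors
#'
#' Fisher-Lee circular correlation between the location and color trajectory
#' errors of one subject (one leg, one condition).
#'
#' @param loc_err,col_err Paired trajectory errors in degrees (length >= 8).
#' @return Circular correlation coefficient in [-1, 1].
#' @export
subject_trajectory_correlation <- function(loc_err, col_err) {
  stopifnot(length(loc_err) == length(col_err))
  if (length(loc_err) < 8)
    stop("need at least 8 paired trials for a stable circular correlation")
  circ_cor(loc_err, col_err)
}

#' Group-level binned trajectory correlation
#'
#' For each subject, trials are sorted by location trajectory error and split
#' into `n_bins` equal-count bins (any remainder spread over the leading
#' bins); the per-bin means of the location and the color trajectory errors
#' are taken, and the subjects x bins points are pooled. Returns the linear
#' (Pearson) correlation over the pooled points with its two-sided p-value,
#' matching the scatter-plus-linear-fit group analysis.
#'
#' @param tables data.frame with columns `subject`, `loc_err`, `col_err`
#'   (one row per trial; trajectory errors in degrees, one leg/condition).
#' @param n_bins Number of bins per subject (default 4).
#' @return List: `r`, `p`, `n_points`, and `points` (data.frame subject, bin,
#'   loc mean, col mean). Subjects with fewer than `n_bins` trials are
#'   excluded with a warning.
#' @export
group_binned_correlation <- function(tables, n_bins = 4) {
  stopifnot(all(c("subject", "loc_err", "col_err") %in% names(tables)),
            n_bins >= 2)
  counts <- table(tables$subject)
  bad <- names(counts)[counts < n_bins]
  if (length(bad)) {
    warning("excluding subjects with < n_bins trials: ",
            paste(bad, collapse = ", "))
    tables <- tables[!tables$subject %in% bad, ]
  }
  pts <- do.call(rbind, lapply(split(tables, tables$subject), function(df) {
    o <- order(df$loc_err)
    n <- nrow(df)
    base <- n %/% n_bins
    sizes <- rep(base, n_bins)
    extra <- n - base * n_bins
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    bin <- rep(seq_len(n_bins), sizes)
    data.frame(subject = df$subject[1], bin = seq_len(n_bins),
               loc = tapply(df$loc_err[o], bin, mean),
               col = tapply(df$col_err[o], bin, mean))
  }))
  rownames(pts) <- NULL
  ct <- stats::cor.test(pts$loc, pts$col)
  list(r = unname(ct$estimate), p = ct$p.value, n_points = nrow(pts),
       points = pts)
}
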