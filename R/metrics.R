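#' Sharpness ratio of an averaged stack
#'
#' The ratio of the number of voxels with intensity exactly 255 (all
#' subjects agree) to the number of voxels with nonzero intensity.
#' Misalignment blurs the average and lowers the ratio, so it increases as
#' the registration protocol tightens.
#'
#' @param avg a [stack_volume()] (typically the real-valued averaged
#'   stack), with at least one voxel > 0.
#' @return value in \[0, 1\].
#' @export
sharpness_ratio <- function(avg) {
  stopifnot(is_stack_volume(avg))
  nz <- sum(avg$data > 0)
  if (nz == 0) stop("degenerate input: volume has no nonzero voxel")
  sum(abs(avg$data - 255) < 1e-9) / nz
}

#' Dice index between two binary volumes
#'
#' `2 |A intersect B| / (|A| + |B|)` with A, B the sets of 255-valued
#' voxels; 1 if both sets are empty (degenerate convention).
#'
#' @param a,b binary [stack_volume()]s on the same grid.
#' @return value in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(is_stack_volume(a), is_stack_volume(b))
  if (!same_grid(a, b)) stop("volumes are on different grids")
  A <- a$data == 255; B <- b$data == 255
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Voxel-wise root mean square error
#'
#' `sqrt(mean((a - b)^2))` over all voxels of the common grid (background
#' included), on the 0--255 intensity scale.
#'
#' @param a,b [stack_volume()]s on the same grid.
#' @export
rmse <- function(a, b) {
  stopifnot(is_stack_volume(a), is_stack_volume(b))
  if (!same_grid(a, b)) stop("volumes are on different grids")
  sqrt(mean((a$data - b$data)^2))
}

#' Align models to a neutral reference for unbiased comparison
#'
#' Registers each binary model to a neutral model (rigid then affine),
#' resamples onto the neutral grid and binarizes at 127.5. Comparing
#' averaged models built from different reference subjects is only
#' meaningful after they are mapped into a common space; using a neutral
#' model from a different group avoids biasing the comparison toward any
#' of the compared models.
#'
#' @param models list of binary [stack_volume()]s.
#' @param neutral binary [stack_volume()]; should not be one of `models`.
#' @param opts registration options.
#' @return list of aligned binary volumes on the neutral grid; models whose
#'   registration did not converge carry attribute `aligned = FALSE`.
#' @export
align_for_comparison <- function(models, neutral,
                                 opts = registration_options()) {
  stopifnot(is_stack_volume(neutral))
  if (is_stack_volume(models)) models <- list(models)
  lapply(models, function(m) {
    r1 <- register_rigid(neutral, m, opts = opts)
    r2 <- register_affine(neutral, m, init = r1$transform, opts = opts)
    if (!r2$converged)
      warning("alignment registration did not converge; model flagged")
    out <- binarize(resample(m, r2$transform, grid_of(neutral)), 127.5)
    attr(out, "aligned") <- r2$converged
    out
  })
}

#' Cross-model comparison report
#'
#' Pairwise Dice and RMSE matrices over a set of (aligned) binary models,
#' RMSE of each model against the averaged model, and summary statistics
#' (mean, SD and coefficient of variation of the off-diagonal Dice values).
#'
#' @param models named list of binary [stack_volume()]s on one grid.
#' @param averaged optional averaged model on the same grid (adds an RMSE
#'   column against it).
#' @param neutral optional neutral model; when given, `models` (and
#'   `averaged`) are first passed through [align_for_comparison()].
#' @param opts registration options for the alignment step.
#' @return A `comparison_report`: list with `dice` and `rmse` matrices,
#'   `rmse_vs_averaged`, and `summary`.
#' @export
comparison_report <- function(models, averaged = NULL, neutral = NULL,
                              opts = registration_options()) {
  if (is.null(names(models)))
    names(models) <- sprintf("model%02d", seq_along(models))
  if (!is.null(neutral)) {
    models <- stats::setNames(align_for_comparison(models, neutral, opts),
                              names(models))
    if (!is.null(averaged))
      averaged <- align_for_comparison(list(averaged), neutral, opts)[[1]]
  }
  n <- length(models)
  D <- diag(1, n); R <- matrix(0, n, n)
  dimnames(D) <- dimnames(R) <- list(names(models), names(models))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        D[i, j] <- D[j, i] <- dice(models[[i]], models[[j]])
        R[i, j] <- R[j, i] <- rmse(models[[i]], models[[j]])
      }
    }
  }
  rva <- if (!is.null(averaged))
    vapply(models, rmse, numeric(1), b = averaged) else NULL
  off <- D[upper.tri(D)]
  summary <- if (length(off) > 0) {
    sdd <- if (length(off) > 1) stats::sd(off) else 0
    list(mean_dice = mean(off), sd_dice = sdd,
         cv_dice = sdd / mean(off))
  } else list(mean_dice = NA_real_, sd_dice = NA_real_, cv_dice = NA_real_)
  structure(list(dice = D, rmse = R, rmse_vs_averaged = rva,
                 summary = summary),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat("Dice matrix:\n"); print(round(x$dice, 4))
  cat("RMSE matrix:\n"); print(round(x$rmse, 2))
  if (!is.null(x$rmse_vs_averaged)) {
    cat("RMSE vs averaged model:\n"); print(round(x$rmse_vs_averaged, 2))
  }
  cat(sprintf("mean Dice %.6f, SD %.6f, CV %.6f\n", x$summary$mean_dice,
              x$summary$sd_dice, x$summary$cv_dice))
  invisible(x)
}

#' Serialize a comparison report
#'
#' @param x a `comparison_report`.
#' @param json_path,csv_prefix output paths; either may be `NULL` to skip.
#' @export
write_comparison_report <- function(x, json_path = NULL, csv_prefix = NULL) {
  stopifnot(inherits(x, "comparison_report"))
  if (!is.null(json_path)) {
    payload <- list(dice = x$dice, rmse = x$rmse,
                    rmse_vs_averaged = x$rmse_vs_averaged,
                    summary = x$summary)
    writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                                matrix = "rowmajor"), json_path)
  }
  if (!is.null(csv_prefix)) {
    utils::write.csv(x$dice, paste0(csv_prefix, "_dice.csv"))
    utils::write.csv(x$rmse, paste0(csv_prefix, "_rmse.csv"))
  }
  invisible(x)
}
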