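#' Modified z-scores (median / MAD)
#'
#' Robust standardisation underlying all outlier decisions in the pipeline:
#' \deqn{z_i = 0.6745\,(x_i - median(x)) / MAD(x)} with the unscaled MAD
#' (median absolute deviation from the median). Values with |z| > 3.5 are
#' conventionally flagged as outliers (Iglewicz--Hoaglin criterion).
#'
#' @param x Numeric vector with at least 3 finite values.
#' @return Numeric vector of modified z-scores (NA where `x` is NA).
#' @examples
#' modified_z(c(1, 2, 3, 4, 100))  # last value ~ 65, clearly flagged
#' @export
modified_z <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 3L) stop("need at least 3 finite values", call. = FALSE)
  m <- stats::median(x[ok])
  mad0 <- stats::median(abs(x[ok] - m))
  if (mad0 == 0) stop("MAD is zero: spread is degenerate", call. = FALSE)
  z <- rep(NA_real_, length(x))
  z[ok] <- 0.6745 * (x[ok] - m) / mad0
  z
}

#' Yeo-Johnson power transformation
#'
#' The piecewise power map defined for all reals, strictly increasing in `x`
#' for every exponent `lambda`:
#' x >= 0: ((x+1)^lambda - 1)/lambda, or log(x+1) when lambda = 0;
#' x < 0: -((-x+1)^(2-lambda) - 1)/(2-lambda), or -log(-x+1) when lambda = 2.
#'
#' @param x Numeric vector.
#' @param lambda Exponent.
#' @return Transformed vector.
#' @examples
#' yeo_johnson(c(-2, 0, 3), 1)  # identity
#' @export
yeo_johnson <- function(x, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  pos <- !is.na(x) & x >= 0
  out <- x
  if (abs(lambda) < 1e-12) {
    out[pos] <- log1p(x[pos])
  } else {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  }
  neg <- !is.na(x) & x < 0
  if (abs(lambda - 2) < 1e-12) {
    out[neg] <- -log1p(-x[neg])
  } else {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  }
  out
}

#' Normality-optimal Yeo-Johnson exponent
#'
#' Chooses lambda in [-5, 5] maximising the Shapiro-Wilk W statistic of the
#' transformed sample (W is monotone in the Shapiro-Wilk p-value at fixed n and
#' numerically stabler). A coarse grid locates the basin; `stats::optimize`
#' refines within the bracketing interval, giving resolution well below the
#' grid step.
#'
#' @param x Numeric vector with at least 8 finite values.
#' @param bounds Search interval for lambda.
#' @param grid_step Coarse-grid step.
#' @return The optimal lambda (scalar).
#' @export
optimize_lambda <- function(x, bounds = c(-5, 5), grid_step = 0.1) {
  x <- x[is.finite(x)]
  if (length(x) < 8L) stop("need at least 8 finite values", call. = FALSE)
  w_of <- function(l) {
    y <- yeo_johnson(x, l)
    if (!all(is.finite(y)) || stats::sd(y) == 0) return(-Inf)
    unname(stats::shapiro.test(y)$statistic)
  }
  grid <- seq(bounds[1], bounds[2], by = grid_step)
  ws <- vapply(grid, w_of, numeric(1))
  best <- which.max(ws)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  if (lo == hi) return(grid[best])
  opt <- stats::optimize(w_of, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-4)
  if (opt$objective >= ws[best]) opt$maximum else grid[best]
}

#' Three-step score preprocessing
#'
#' Normalises, cleans and standardises the averaged score table, per test and
#' with the two groups merged:
#' \enumerate{
#'   \item remove outliers by modified z (|z| > 3.5);
#'   \item optimise the Yeo-Johnson exponent on the remaining values to
#'     maximise Shapiro-Wilk normality;
#'   \item reinsert the removed values, transform everything with the chosen
#'     exponent, and repeat the modified-z outlier removal on the transformed
#'     data.
#' }
#' Surviving values are standardised to mean 0 / SD 1 and the sign of every
#' test except VA and HoneyW is reversed so that higher scores always mean
#' better performance. A test column whose spread is degenerate is passed
#' through untransformed with a warning; other tests are unaffected.
#'
#' @param scores Averaged score tibble from [average_repetitions()]
#'   (`participant_id`, `group`, `test`, `score`).
#' @param z_cut Modified z cutoff.
#' @param flip_exempt Tests whose sign is not reversed.
#' @return A list with `scores` (same shape, `score` replaced by the
#'   preprocessed value, removed outliers as NA) and `transforms`, one row per
#'   test: `lambda`, `w_before`, `w_after`, `n_outliers_pass1`,
#'   `n_outliers_pass2`, `sign_flipped`.
#' @export
preprocess_scores <- function(scores, z_cut = 3.5,
                              flip_exempt = c("VA", "HoneyW")) {
  stopifnot(all(c("participant_id", "test", "score") %in% names(scores)))
  transforms <- list()
  out <- scores |>
    dplyr::group_by(.data$test) |>
    dplyr::group_modify(function(d, key) {
      x <- d$score
      res <- tryCatch(
        preprocess_column(x, z_cut),
        error = function(e) {
          warning("test ", key$test, " passed through unpreprocessed: ",
                  conditionMessage(e), call. = FALSE)
          list(value = scale_safe(x), lambda = NA_real_,
               w_before = NA_real_, w_after = NA_real_,
               n1 = 0L, n2 = 0L)
        }
      )
      flip <- !(key$test %in% flip_exempt)
      transforms[[key$test]] <<- tibble::tibble(
        test = key$test, lambda = res$lambda,
        w_before = res$w_before, w_after = res$w_after,
        n_outliers_pass1 = res$n1, n_outliers_pass2 = res$n2,
        sign_flipped = flip
      )
      d$score <- if (flip) -res$value else res$value
      d
    }) |>
    dplyr::ungroup()
  list(
    scores = out[, union(names(scores), "test")],
    transforms = dplyr::bind_rows(transforms) |>
      dplyr::arrange(match(.data$test, unique(scores$test)))
  )
}

scale_safe <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

preprocess_column <- function(x, z_cut) {
  ok <- is.finite(x)
  z1 <- rep(NA_real_, length(x))
  z1[ok] <- modified_z(x[ok])
  inlier <- ok & abs(z1) <= z_cut
  w_before <- unname(stats::shapiro.test(x[inlier])$statistic)
  lambda <- optimize_lambda(x[inlier])
  y <- yeo_johnson(x, lambda)            # outliers reinserted here
  z2 <- rep(NA_real_, length(y))
  z2[ok] <- modified_z(y[ok])
  keep <- ok & abs(z2) <= z_cut
  w_after <- unname(stats::shapiro.test(y[keep])$statistic)
  value <- rep(NA_real_, length(x))
  value[keep] <- as.numeric(scale(y[keep]))
  list(value = value, lambda = lambda, w_before = w_before, w_after = w_after,
       n1 = sum(ok & !inlier), n2 = sum(ok & !keep))
}
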