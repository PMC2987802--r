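# Intron-count dynamics: the distribution of species over intron counts and
# the logarithmic decay model y = a*ln(x) + b fitted to it. A logarithmic
# decrease of the number of species carrying x introns — rather than the
# Gaussian expected under purely random gain/loss — is the signature of a
# net drift of these genes toward intron loss.

#' Species counts per intron count
#'
#' @param matrix A `landscape_matrix`.
#' @return Data frame with columns `n_introns` (observed intron count,
#'   including 0) and `n_species`; `n_species` sums to the number of
#'   species.
#' @export
intron_count_histogram <- function(matrix) {
  stopifnot(inherits(matrix, "landscape_matrix"))
  counts <- colSums(unclass(matrix) != "absent")
  tab <- table(counts)
  data.frame(n_introns = as.integer(names(tab)),
             n_species = as.integer(tab))
}

#' Fit the logarithmic intron-count decay model
#'
#' Least-squares fit of `y = a * ln(x) + b` to points
#' `(x = intron count, y = species count)`. Because `ln(0)` is undefined,
#' `x_policy = "exclude_zero"` (default) drops the x = 0 point, while
#' `"shift_plus_one"` fits on `ln(x + 1)` so intronless species take part.
#'
#' @param points Data frame with columns `n_introns`, `n_species` (as from
#'   [intron_count_histogram()]), or a two-column matrix/data frame (x, y).
#' @param x_policy `"exclude_zero"` or `"shift_plus_one"`.
#' @return Object of class `dynamics_fit`: `a` (slope of ln x), `b`
#'   (intercept), `r_squared`, `n_points`, `x_policy`.
#' @export
fit_log_model <- function(points, x_policy = c("exclude_zero",
                                               "shift_plus_one")) {
  x_policy <- match.arg(x_policy)
  if (all(c("n_introns", "n_species") %in% names(points))) {
    x <- points$n_introns; y <- points$n_species
  } else {
    x <- points[[1]]; y <- points[[2]]
  }
  if (x_policy == "exclude_zero") {
    keep <- x > 0
    x <- x[keep]; y <- y[keep]
    lx <- log(x)
  } else {
    lx <- log(x + 1)
  }
  if (length(unique(lx)) < 2) stop("degenerate fit: fewer than 2 distinct x")
  fit <- lm(y ~ lx)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         r_squared = r2, n_points = length(x), x_policy = x_policy),
    class = "dynamics_fit")
}

#' @export
print.dynamics_fit <- function(x, ...) {
  cat(sprintf("<dynamics_fit> y = %.4f ln(x) + %.4f  (R^2 = %.3f, n = %d, %s)\n",
              x$a, x$b, x$r_squared, x$n_points, x$x_policy))
  invisible(x)
}
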