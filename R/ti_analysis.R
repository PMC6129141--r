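#' Integrate a thermodynamic-integration window table
#'
#' Trapezoidal quadrature of the window means of dH/dlambda over the
#' lambda grid, without extrapolation beyond the tabulated endpoints.
#' Simpson's rule is available for smooth integrands on odd-length grids.
#'
#' @param table a [ti_table()].
#' @param method `"trapezoid"` (default) or `"simpson"`.
#' @return the free-energy change in kcal/mol.
#' @export
integrate_ti <- function(table, method = c("trapezoid", "simpson")) {
  method <- match.arg(method)
  if (nrow(table) < 2L) stop("a TI table needs at least two windows")
  if (method == "trapezoid")
    pracma::trapz(table$lambda, table$dhdl)
  else
    .simpson_nonuniform(table$lambda, table$dhdl)
}

# Composite Simpson on possibly non-uniform grids; falls back to a
# trapezoid on the last interval when the window count is even.
.simpson_nonuniform <- function(x, y) {
  n <- length(x)
  total <- 0
  i <- 1L
  while (i + 2L <= n) {
    h0 <- x[i + 1L] - x[i]
    h1 <- x[i + 2L] - x[i + 1L]
    total <- total + (h0 + h1) / 6 *
      ((2 - h1 / h0) * y[i] +
         (h0 + h1)^2 / (h0 * h1) * y[i + 1L] +
         (2 - h0 / h1) * y[i + 2L])
    i <- i + 2L
  }
  if (i < n) total <- total + (x[n] - x[n - 1L]) * (y[n] + y[n - 1L]) / 2
  total
}

#' Combine forward and backward TI estimates
#'
#' Integrates both direction tables, reports their mean as the free-energy
#' estimate, the two-point sample standard deviation (|forward - backward|
#' / sqrt(2)) as the error, and the hysteresis |forward - backward| as a
#' convergence diagnostic.
#'
#' @param forward,backward [ti_table()]s.
#' @param method quadrature method, see [integrate_ti()].
#' @param correction optional additive free-energy correction in kcal/mol
#'   (e.g. a restraint-release term computed elsewhere); defaults to 0.
#' @return object of class `ti_result` with fields `dG_forward`,
#'   `dG_backward`, `dG_mean`, `dG_err`, `hysteresis`, `n_windows`.
#' @export
combine_directions <- function(forward, backward,
                               method = c("trapezoid", "simpson"),
                               correction = 0) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(forward$lambda, backward$lambda)))
    warning("forward and backward lambda grids differ; integrating each on its own grid")
  dgf <- integrate_ti(forward, method) + correction
  dgb <- integrate_ti(backward, method) + correction
  structure(
    list(dG_forward = dgf, dG_backward = dgb,
         dG_mean = (dgf + dgb) / 2,
         dG_err = stats::sd(c(dgf, dgb)),
         hysteresis = abs(dgf - dgb),
         n_windows = nrow(forward)),
    class = "ti_result"
  )
}

#' @export
print.ti_result <- function(x, ...) {
  cat(sprintf(
    "<ti_result> dG = %.3f +/- %.3f kcal/mol (forward %.3f, backward %.3f, hysteresis %.3f, %d windows)\n",
    x$dG_mean, x$dG_err, x$dG_forward, x$dG_backward, x$hysteresis,
    x$n_windows))
  invisible(x)
}

#' Compare solvation free energies between ion placements
#'
#' Pairwise free-energy differences between labelled TI results (e.g. the
#' Mg2+ ion in bulk water versus bound at the nucleotide in either
#' coordination state), with errors propagated in quadrature, and a verdict
#' naming the most favourable (lowest free energy) placement — `"tie"`
#' when the top two placements are inseparable within their combined error.
#'
#' @param results named list of [combine_directions()] results.
#' @return object of class `placement_comparison` with `ddG`
#'   (data.frame: `a`, `b`, `ddG`, `err`), antisymmetric under label swap,
#'   and `verdict`.
#' @export
compare_placements <- function(results) {
  if (length(results) < 2L) stop("need at least two labelled results")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be named by placement label")
  labs <- names(results)
  rows <- list()
  for (a in seq_along(labs)) {
    for (b in seq_along(labs)) {
      if (a == b) next
      rows[[length(rows) + 1L]] <- data.frame(
        a = labs[a], b = labs[b],
        ddG = results[[a]]$dG_mean - results[[b]]$dG_mean,
        err = sqrt(results[[a]]$dG_err^2 + results[[b]]$dG_err^2),
        stringsAsFactors = FALSE
      )
    }
  }
  ddG <- do.call(rbind, rows)
  means <- vapply(results, `[[`, numeric(1), "dG_mean")
  ord <- order(means)
  best <- labs[ord[1]]; second <- labs[ord[2]]
  gap <- abs(means[ord[1]] - means[ord[2]])
  comb <- sqrt(results[[best]]$dG_err^2 + results[[second]]$dG_err^2)
  structure(
    list(ddG = ddG,
         verdict = if (gap <= comb) "tie" else best,
         most_favourable = best, margin = gap, margin_err = comb),
    class = "placement_comparison"
  )
}

#' @export
print.placement_comparison <- function(x, ...) {
  cat("<placement_comparison> most favourable: ", x$verdict,
      sprintf(" (margin %.2f +/- %.2f kcal/mol)\n", x$margin, x$margin_err),
      sep = "")
  print(x$ddG)
  invisible(x)
}
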