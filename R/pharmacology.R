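#' @include utils.R
NULL

#' Convert a tissue drug concentration from ug/g to nM
#'
#' Dimensional analysis: ug drug / g tissue, times tissue density (g/mL),
#' gives ug/mL; dividing by the molecular weight (g/mol) gives umol/L,
#' i.e. 1e3 nM per unit. The default density and molecular weight are those
#' of doxorubicin in brain tissue (d = 1.046 g/mL, MW = 579.98 g/mol).
#'
#' @param ugPerG Concentration in micrograms of drug per gram of tissue.
#' @param density Tissue density in g/mL.
#' @param mw Molecular weight in g/mol.
#' @return Concentration in nM.
#' @examples
#' ugPerGToNanomolar(0.3)                 # ~541 nM for doxorubicin in brain
#' ugPerGToNanomolar(1, density = 1, mw = 1e6)   # 1 nM
#' @export
ugPerGToNanomolar <- function(ugPerG, density = 1.046, mw = 579.98) {
  if (any(ugPerG < 0)) stop("'ugPerG' must be >= 0")
  if (density <= 0) stop("'density' must be > 0")
  if (mw <= 0) stop("'mw' must be > 0")
  ugPerG * density * 1e6 / mw
}

#' Fold of a concentration over an IC50
#'
#' @param conc Concentration, nM.
#' @param ic50 IC50 in the same units, > 0.
#' @return Integer fold (rounded).
#' @examples
#' foldOverIC50(690, 7.1)    # 97
#' foldOverIC50(690, 86.6)   # 8
#' @export
foldOverIC50 <- function(conc, ic50) {
  if (!is.finite(ic50) || ic50 <= 0) stop("'ic50' must be > 0")
  round(conc / ic50)
}

#' Read a dose-response plate table
#'
#' @param path CSV with columns \code{concentration_nM}, \code{well},
#'   \code{confluence_pct}.
#' @return A validated data.frame.
#' @export
readDoseResponse <- function(path) {
  df <- utils::read.csv(path)
  need <- c("concentration_nM", "confluence_pct")
  if (!all(need %in% names(df)))
    stop("plate table must have columns ", paste(need, collapse = ", "))
  .checkPlate(df)
  df
}

.checkPlate <- function(plate) {
  if (any(plate$concentration_nM < 0)) stop("concentrations must be >= 0")
  if (any(plate$confluence_pct < 0 | plate$confluence_pct > 100))
    stop("confluence must be within [0, 100] percent")
  invisible(plate)
}

#' Four-parameter logistic IC50 fit
#'
#' Fits the variable-slope logistic
#' \deqn{y = bottom + (top - bottom) / (1 + 10^{h (\log_{10} c - \log_{10} IC_{50})})}
#' to the mean confluence per concentration, in log10-concentration space
#' for conditioning. The IC50 is the concentration at half-maximal
#' inhibition between the fitted top and bottom; its standard error is
#' delta-method-propagated from log10 space.
#'
#' @param plate data.frame with columns \code{concentration_nM} and
#'   \code{confluence_pct} (a \code{well} column is allowed and ignored).
#'   At least 4 distinct positive concentrations spanning the transition.
#' @return An \linkS4class{Ic50Fit}.
#' @export
fitIC50 <- function(plate) {
  need <- c("concentration_nM", "confluence_pct")
  if (!all(need %in% names(plate)))
    stop("plate table must have columns ", paste(need, collapse = ", "))
  .checkPlate(plate)
  plate <- plate[plate$concentration_nM > 0, , drop = FALSE]
  means <- tapply(plate$confluence_pct, plate$concentration_nM, mean)
  conc <- as.numeric(names(means))
  y <- as.numeric(means)
  if (length(conc) < 4L)
    stop("need at least 4 distinct positive concentrations")
  if (diff(range(y)) < 1e-6)
    stop("no dose dependence in the plate: IC50 fit cannot converge")
  lx <- log10(conc)
  top0 <- max(y); bot0 <- min(y)
  mid <- (top0 + bot0) / 2
  l0 <- lx[which.min(abs(y - mid))]
  fn <- function(p) {     # p = (top, bottom, logIC50, hill)
    p[1L] + (p[2L] - p[1L]) / (1 + 10^(p[4L] * (p[3L] - lx))) - y
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = c(top = top0, bottom = bot0, logIC50 = l0, hill = 1),
    fn = fn,
    lower = c(-Inf, -Inf, min(lx) - 2, 0.05),
    upper = c(Inf, Inf, max(lx) + 2, 20),
    control = minpack.lm::nls.lm.control(maxiter = 500)))
  p <- coef(fit)
  if (any(!is.finite(p))) stop("IC50 fit did not converge")
  if (p["top"] - p["bottom"] < 1e-3)
    stop("no dose dependence in the plate: IC50 fit cannot converge")
  seLog <- tryCatch(summary(fit)$coefficients["logIC50", "Std. Error"],
                    error = function(e) NA_real_)
  ic50 <- 10^unname(p["logIC50"])
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  new("Ic50Fit", ic50 = ic50, hill = unname(p["hill"]),
      top = unname(p["top"]), bottom = unname(p["bottom"]),
      se = if (is.finite(seLog)) log(10) * ic50 * seLog else NA_real_,
      r2 = 1 - sse / sst)
}
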