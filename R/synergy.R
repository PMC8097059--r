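# Dose-response 4PL fitting with IC50 extraction and Bliss-independence
# synergy scoring.

#' Fit a four-parameter logistic dose-response curve
#'
#' Unweighted least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (dose / IC50)^hill)`
#' on log10 dose, with multi-start initialization from data quantiles.
#' The hill slope is unconstrained in sign; the IC50 is kept within
#' 10^4-fold of the observed dose range. A response range below
#' `min_range` means the curve carries no dose information and is an
#' error.
#'
#' @param table Dose-response data.frame with columns `dose` (uM, > 0)
#'   and `response` (surviving fraction); at least 4 distinct doses.
#' @param min_range Minimum observed response range ("noise floor").
#' @return List with `bottom`, `top`, `ic50`, `hill`, `rss`, `converged`.
#'   A non-converged fit carries `ic50 = NA`.
#' @export
fit_4pl <- function(table, min_range = 0.05) {
  dose <- table$dose
  y <- table$response
  if (any(is.na(dose)) || any(dose <= 0)) stop2("doses must be positive")
  if (any(!is.finite(y))) stop2("responses must be finite")
  if (length(unique(dose)) < 4) stop2("need >= 4 distinct doses")
  if (diff(range(y)) < min_range) stop2("no dose dependence")
  lx <- log10(dose)
  lo <- min(lx) - 4
  hi <- max(lx) + 4
  model <- y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - lic50)))
  q <- stats::quantile(lx, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- expand.grid(lic50 = q, hill = c(-1, 1, -2, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        model,
        data = data.frame(lx = lx, y = y),
        start = list(bottom = stats::quantile(y, 0.05, names = FALSE),
                     top = stats::quantile(y, 0.95, names = FALSE),
                     lic50 = starts$lic50[i], hill = starts$hill[i]),
        lower = c(bottom = -Inf, top = -Inf, lic50 = lo, hill = -Inf),
        upper = c(bottom = Inf, top = Inf, lic50 = hi, hill = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                   ic50 = unname(10^cf["lic50"]), hill = unname(cf["hill"]),
                   rss = rss, converged = fit$convInfo$isConv %||% TRUE)
    }
  }
  if (is.null(best)) {
    return(list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
                hill = NA_real_, rss = NA_real_, converged = FALSE))
  }
  # report the curve with bottom below top (swap is a hill sign flip)
  if (best$bottom > best$top) {
    tmp <- best$bottom; best$bottom <- best$top; best$top <- tmp
    best$hill <- -best$hill
  }
  if (!best$converged) best$ic50 <- NA_real_
  best
}

#' Bliss independence index
#'
#' Under Bliss independence two drugs act independently and the expected
#' combination surviving fraction is the product of the single-agent
#' surviving fractions. The index is `S_A * S_B - S_AB`: positive means
#' synergy (the combination kills more than expected), negative
#' antagonism, zero an additive effect. Note the sign convention is fixed
#' by the synergy inequality `S_AB < S_A * S_B`; the additive zero is
#' convention-independent.
#'
#' @param S_A,S_B,S_AB Surviving fractions in `[0, 1.2]` (values slightly
#'   above 1 are tolerated for assay noise). Vectors are recycled.
#' @return Data.frame with `S_A`, `S_B`, `S_AB`, `index` and a `call`
#'   column (`synergy` / `antagonism` / `additive`).
#' @export
bliss_index <- function(S_A, S_B, S_AB) {
  vals <- c(S_A, S_B, S_AB)
  if (any(is.na(vals)) || any(vals < 0)) stop2("surviving fractions must be >= 0")
  if (any(vals > 1.2)) stop2("surviving fractions above 1.2 are not plausible")
  index <- S_A * S_B - S_AB
  data.frame(S_A = S_A, S_B = S_B, S_AB = S_AB, index = index,
             call = ifelse(index > 0, "synergy",
                           ifelse(index < 0, "antagonism", "additive")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare IC50s between two arms
#'
#' Fold-change of geometric-mean IC50s and, when both arms carry at least
#' two replicate fits, a two-sided t test on the log-transformed
#' replicate IC50s.
#'
#' @param ic50_a,ic50_b Numeric vectors of replicate IC50 estimates
#'   (uM, > 0) for the reference and comparison arms.
#' @return List with `fold_change` (`b / a` on the geometric-mean scale),
#'   `p` (NA when either arm has < 2 replicates) and the per-arm
#'   geometric means.
#' @export
compare_ic50 <- function(ic50_a, ic50_b) {
  ic50_a <- ic50_a[!is.na(ic50_a)]
  ic50_b <- ic50_b[!is.na(ic50_b)]
  if (length(ic50_a) == 0 || length(ic50_b) == 0) stop2("no converged IC50s")
  if (any(c(ic50_a, ic50_b) <= 0)) stop2("IC50s must be positive")
  la <- log(ic50_a)
  lb <- log(ic50_b)
  fold <- exp(mean(lb) - mean(la))
  p <- NA_real_
  if (length(la) >= 2 && length(lb) >= 2) {
    if (stats::sd(c(la, lb)) == 0) {
      p <- 1
    } else {
      p <- tryCatch(stats::t.test(lb, la)$p.value, error = function(e) NA_real_)
    }
  }
  list(fold_change = fold, p = p,
       geomean_a = exp(mean(la)), geomean_b = exp(mean(lb)),
       n_a = length(la), n_b = length(lb))
}
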