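#' Standardized local sensitivity coefficient
#'
#' Measures how strongly a design function F responds to a small relative
#' perturbation of one parameter. The parameter is multiplied by
#' (1 + epsilon) and the standardized coefficient is
#' \deqn{LSC = |F(\theta_i (1+\varepsilon)) - F(\theta)| / |\varepsilon|,}
#' i.e. the absolute finite-difference derivative scaled by the parameter
#' value (a semi-elasticity). Dividing the parameter change by the parameter
#' itself makes coefficients comparable across parameters with different
#' magnitudes and units. The raw-derivative variant
#' \eqn{|\Delta F| / |\Delta \theta_i|} is available with
#' \code{standardize = FALSE}.
#'
#' @param design_fn Function of a \code{\link{rate_params}} object returning
#'   a scalar (typically the SSD against a data set).
#' @param params Baseline \code{\link{rate_params}}.
#' @param which One of \code{"k1"}, \code{"k2"}, \code{"a"}, \code{"b"}.
#' @param epsilon Signed relative perturbation (non-zero), e.g. 0.01 for +1%.
#' @param standardize Scale by the parameter value (default TRUE).
#' @return The non-negative coefficient.
#' @examples
#' tc <- mcf7_timecourse()
#' f <- function(p) sum_squared_deviations(p, r0 = tc$ratio[1], data = tc)
#' standardized_lsc(f, rate_params(0.2, 0.22, 0.01, 0.001), "a", 0.05)
#' @export
standardized_lsc <- function(design_fn, params, which, epsilon,
                             standardize = TRUE) {
  params <- as_rate_params(params)
  which <- match.arg(which, c("k1", "k2", "a", "b"))
  if (!is.finite(epsilon) || epsilon == 0)
    stop("epsilon must be non-zero", call. = FALSE)
  theta <- params[[which]]
  if (theta <= 0)
    stop("relative perturbation undefined for ", which, " = 0",
         call. = FALSE)
  perturbed <- unclass(params)
  perturbed[[which]] <- theta * (1 + epsilon)
  df <- design_fn(do.call(rate_params, perturbed)) - design_fn(params)
  if (standardize) abs(df) / abs(epsilon) else abs(df) / abs(epsilon * theta)
}

#' Table of local sensitivity coefficients for the four rates
#'
#' Perturbs each rate by +/-1%, 2%, 3%, 4% and 5% of its value (ten
#' perturbations per parameter) around a fitted baseline and records the
#' standardized LSC of the SSD design function for each, together with the
#' per-parameter mean and sample standard deviation.
#'
#' @param data A \code{\link{timecourse}} the SSD is evaluated against.
#' @param params Baseline (fitted) \code{\link{rate_params}}.
#' @param r0 Initial ratio for the model curve (default: first observation).
#' @param epsilons Magnitudes of the relative perturbations; both signs are
#'   applied to each.
#' @param standardize Passed to \code{\link{standardized_lsc}}.
#' @return An object of class \code{"csc_lsc_table"}: list with
#'   \code{values} (data.frame \code{parameter}, \code{epsilon},
#'   \code{lsc}; 4 x 10 rows), \code{summary} (per-parameter mean and sd),
#'   \code{baseline_ssd}, \code{params}.
#' @examples
#' lsc_table(mcf7_timecourse(), rate_params(0.2, 0.22, 0.01, 0.001))
#' @export
lsc_table <- function(data, params, r0 = NULL,
                      epsilons = c(0.01, 0.02, 0.03, 0.04, 0.05),
                      standardize = TRUE) {
  params <- as_rate_params(params)
  stopifnot(inherits(data, "csc_timecourse"))
  if (is.null(r0)) r0 <- data$ratio[1L]
  f <- function(p) sum_squared_deviations(p, r0, data)
  pars <- c("k1", "k2", "a", "b")
  eps <- as.numeric(rbind(epsilons, -epsilons))
  values <- expand.grid(epsilon = eps, parameter = pars,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)[, 2:1]
  values$lsc <- mapply(function(w, e) standardized_lsc(f, params, w, e,
                                                       standardize),
                       values$parameter, values$epsilon)
  summ <- do.call(rbind, lapply(pars, function(w) {
    v <- values$lsc[values$parameter == w]
    data.frame(parameter = w, mean = mean(v), sd = stats::sd(v))
  }))
  structure(list(values = values, summary = summ,
                 baseline_ssd = f(params), params = params),
            class = "csc_lsc_table")
}

#' @export
print.csc_lsc_table <- function(x, ...) {
  cat("Standardized local sensitivity coefficients of the SSD\n")
  cat(sprintf("  baseline SSD = %.6g\n", x$baseline_ssd))
  print(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}

#' One-way ANOVA across groups of sensitivity coefficients
#'
#' Standard between/within sum-of-squares decomposition, computed through
#' \code{stats::aov}. The degenerate case of zero variance everywhere with
#' equal means is reported as F = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups of >= 2 values).
#' @return A list of class \code{"csc_anova"}: \code{F}, \code{df} (between,
#'   within), \code{p}.
#' @examples
#' oneway_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(10, 11, 12)))
#' @export
oneway_anova <- function(groups) {
  check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  if (stats::var(y) == 0)
    return(structure(list(F = 0, df = c(df1, df2), p = 1),
                     class = "csc_anova"))
  tab <- stats::anova(stats::aov(y ~ g))
  structure(list(F = tab$`F value`[1L],
                 df = c(tab$Df[1L], tab$Df[2L]),
                 p = tab$`Pr(>F)`[1L]),
            class = "csc_anova")
}

#' @export
print.csc_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p))
  invisible(x)
}

#' Tamhane's T2 all-pairs comparisons
#'
#' Post-hoc pairwise comparisons for groups with unequal variances: each
#' pair is compared with a Welch t statistic on Welch-Satterthwaite degrees
#' of freedom, and the p-values are adjusted with the Sidak multiplicity
#' correction over all \eqn{m = k(k-1)/2} pairs
#' (\eqn{p_{adj} = 1 - (1 - p)^m}). With two groups this reduces to a plain
#' Welch test.
#'
#' @param groups Named list of numeric vectors (>= 2 groups of >= 2 values).
#' @param alpha Significance level for the \code{significant} flag.
#' @return A data.frame with one row per unordered pair: \code{group1},
#'   \code{group2}, \code{t}, \code{df}, \code{p}, \code{p_adj},
#'   \code{significant}.
#' @examples
#' tamhane_t2(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(10, 11, 12)))
#' @export
tamhane_t2 <- function(groups, alpha = 0.05) {
  check_groups(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2L)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    x <- groups[[i1]]; y <- groups[[i2]]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      tt <- list(statistic = if (eq) 0 else Inf,
                 parameter = length(x) + length(y) - 2, p.value = if (eq) 1 else 0)
    } else {
      tt <- stats::t.test(x, y)  # Welch by default
    }
    data.frame(group1 = nms[i1], group2 = nms[i2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, out)
  out$p_adj <- 1 - (1 - out$p)^m
  out$significant <- out$p_adj < alpha
  out
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  if (any(!vapply(groups, is.numeric, logical(1))))
    stop("groups must be numeric vectors", call. = FALSE)
  invisible(TRUE)
}

#' Full sensitivity analysis at a fitted parameter set
#'
#' Convenience wrapper: builds the LSC table, runs the one-way ANOVA across
#' the four parameter groups, and the Tamhane T2 pairwise comparisons.
#'
#' @inheritParams lsc_table
#' @param alpha Significance level for the pairwise flags.
#' @return A list of class \code{"csc_sensitivity"}: \code{lsc} (the
#'   \code{\link{lsc_table}}), \code{anova}, \code{pairwise}.
#' @export
sensitivity_analysis <- function(data, params, r0 = NULL,
                                 epsilons = c(0.01, 0.02, 0.03, 0.04, 0.05),
                                 standardize = TRUE, alpha = 0.05) {
  lsc <- lsc_table(data, params, r0, epsilons, standardize)
  groups <- split(lsc$values$lsc, lsc$values$parameter)[c("k1", "k2", "a", "b")]
  structure(list(lsc = lsc, anova = oneway_anova(groups),
                 pairwise = tamhane_t2(groups, alpha)),
            class = "csc_sensitivity")
}

#' @export
print.csc_sensitivity <- function(x, ...) {
  print(x$lsc)
  print(x$anova)
  cat("Tamhane T2 pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
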