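#' Read an ordinal coding scheme
#'
#' The coding scheme maps raw category labels of each ecological variable to
#' consecutive integer codes, one variable at a time, as a TSV with columns
#' `variable`, `category`, `code`. A variable whose single row has category
#' `<metric>` is passed through unchanged (its original metric values are
#' used). An example scheme for eleven genetic/ecological variables ships in
#' `inst/extdata/eco_coding_example.tsv`.
#'
#' @param path TSV path.
#' @return Named list: for each variable either the string `"metric"` or a
#'   named numeric vector mapping category -> code.
#' @export
read_coding_scheme <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("variable", "category", "code")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("coding scheme missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- list()
  for (v in unique(d$variable)) {
    rows <- d[d$variable == v, , drop = FALSE]
    if (nrow(rows) == 1 && rows$category == "<metric>") {
      out[[v]] <- "metric"
    } else {
      codes <- as.numeric(rows$code)
      if (anyNA(codes)) stop("non-numeric code for variable ", v, call. = FALSE)
      out[[v]] <- setNames(codes, rows$category)
    }
  }
  out
}

#' Encode raw ecological variables to ordinal codes
#'
#' Applies a coding scheme to a raw species-by-variable profile. Ordinal
#' variables are mapped category -> integer code; metric variables are passed
#' through as numeric. Missing raw values stay missing (and later shrink the
#' pairwise n of each correlation cell). A raw value absent from the
#' scheme's map is an error naming the variable and the value.
#'
#' @param raw data frame with a `species_id` column plus one column per
#'   variable (character or numeric).
#' @param scheme result of [read_coding_scheme()], or an equivalent list.
#' @return Data frame of class `eco_profile`: `species_id` plus numeric
#'   columns for every variable in the scheme.
#' @export
ordinal_encode <- function(raw, scheme) {
  stopifnot("species_id" %in% names(raw))
  out <- data.frame(species_id = raw$species_id, stringsAsFactors = FALSE)
  for (v in names(scheme)) {
    if (!v %in% names(raw)) stop("profile lacks variable: ", v, call. = FALSE)
    x <- raw[[v]]
    if (identical(scheme[[v]], "metric")) {
      out[[v]] <- as.numeric(x)
    } else {
      map <- scheme[[v]]
      xc <- as.character(x)
      known <- is.na(xc) | xc %in% names(map)
      if (!all(known)) {
        stop("variable ", v, ": value(s) not in coding scheme: ",
             paste(unique(xc[!known]), collapse = ", "), call. = FALSE)
      }
      out[[v]] <- unname(map[xc])
    }
  }
  class(out) <- c("eco_profile", "data.frame")
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes the Spearman coefficient as the Pearson correlation of midranks
#' (ties allowed). The two-sided p-value is the exact permutation tail mass
#' (full enumeration of all n! orderings) for `n <= exact_max`, and the
#' t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom otherwise.
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @param exact_max largest n for which the exact enumeration is used
#'   (default 10).
#' @return A list with `r_s`, `p`, `n`, `method` (`"exact"` or `"t"`), and
#'   `degenerate` (`TRUE` when either midrank vector has zero variance, in
#'   which case `r_s` and `p` are `NA`).
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))$r_s  # 0.8
spearman_rho <- function(x, y, exact_max = 10) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(r_s = NA_real_, p = NA_real_, n = n, method = "none",
                degenerate = TRUE))
  }
  r <- cor(rx, ry)
  if (n <= exact_max) {
    p <- .spearman_perm_pvalue(rx, ry)
    method <- "exact"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t"
  }
  list(r_s = r, p = min(p, 1), n = n, method = method, degenerate = FALSE)
}

#' Eta coefficient (correlation ratio)
#'
#' Association between a categorical factor and a quantitative response:
#' `eta = sqrt(SS_between / SS_total)`, in `[0, 1]`. Direction matters — the
#' grouping variable is the independent variable, the response the dependent
#' one. `eta = 0` iff all group means are equal; `eta = 1` iff the response
#' is constant within every group while group means differ.
#'
#' @param groups factor (or coercible) of group labels.
#' @param y numeric response; pairs with missing values are dropped.
#' @return A list with `eta`, `n`, `k` (non-empty groups) and `degenerate`
#'   (`TRUE`, with `eta = NA`, when the response is constant overall).
#' @export
#' @examples
#' eta_coefficient(c("A", "A", "B", "B"), c(1, 2, 4, 6))$eta  # 0.911...
eta_coefficient <- function(groups, y) {
  ok <- complete.cases(groups, y)
  g <- factor(groups[ok]); y <- as.numeric(y[ok])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  if (ss_total == 0) {
    return(list(eta = NA_real_, n = length(y), k = nlevels(g),
                degenerate = TRUE))
  }
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_between <- sum(ns * (means - gm)^2)
  list(eta = sqrt(ss_between / ss_total), n = length(y), k = nlevels(g),
       degenerate = FALSE)
}

#' Power of the correlation test via the Fisher z-transform
#'
#' Probability of rejecting the null of zero correlation in a two-sided
#' level-`alpha` test, given a true correlation `r` and sample size `n`,
#' using the variance-stabilising transform `z = atanh(r)` with standard
#' error `1/sqrt(n - 3)`:
#' `power = Phi(z*sqrt(n-3) - z_{1-alpha/2}) + Phi(-z*sqrt(n-3) - z_{1-alpha/2})`.
#' At `r = 0` the power equals `alpha` exactly; `|r| = 1` returns 1 by
#' continuity.
#'
#' @param r true (or observed) correlation, `|r| <= 1`.
#' @param n sample size, `n >= 4`.
#' @param alpha test level in (0, 1); default 0.05.
#' @return Power in `[alpha, 1]`.
#' @export
fisher_z_power <- function(r, n, alpha = 0.05) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, abs(r) <= 1)
  if (abs(r) == 1) return(1)
  z <- atanh(r)
  q <- qnorm(1 - alpha / 2)
  pnorm(z * sqrt(n - 3) - q) + pnorm(-z * sqrt(n - 3) - q)
}

#' Multiple linear regression by least squares
#'
#' Ordinary least-squares fit of `y` on the columns of `X` (an intercept is
#' added). Rank-deficient designs are rejected with a message listing the
#' collinear columns.
#'
#' @param y numeric response.
#' @param X numeric matrix or data frame of predictors (may have zero
#'   columns for an intercept-only model).
#' @return A list with `coefficients`, `se`, `t`, `p` (partial t tests),
#'   `r_squared`, `residuals` and `fitted`.
#' @export
ols_regression <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- length(y)
  if (n <= ncol(X) + 1) stop("need n > number of predictors + 1", call. = FALSE)
  M <- cbind(`(Intercept)` = 1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dep <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- lm(y ~ ., data = data.frame(y = y, X, check.names = TRUE))
  sm <- summary(fit)
  list(coefficients = coef(fit),
       se = sm$coefficients[, "Std. Error"],
       t = sm$coefficients[, "t value"],
       p = sm$coefficients[, "Pr(>|t|)"],
       r_squared = sm$r.squared,
       residuals = unname(fit$residuals),
       fitted = unname(fit$fitted.values))
}

#' Correlation battery between family frequencies and ecological variables
#'
#' For each sub-family frequency column (`rec_luxr`, `luxr`, `other`,
#' `total`) crossed with each encoded ecological variable, computes the
#' Spearman correlation with its p-value, the Fisher-z power at the observed
#' coefficient, and the Eta coefficient (variable as grouping factor,
#' frequency as dependent). Missing data are handled pairwise, so n varies
#' by cell. Cells with fewer than 3 overlapping species are flagged missing
#' (all statistics `NA`).
#'
#' @param subfamilies data frame from [census_subfamilies()] (columns
#'   `species_id`, `rec_luxr`, `luxr`, `other`, `total`).
#' @param eco an `eco_profile` from [ordinal_encode()] (or any data frame
#'   with `species_id` plus numeric variable columns).
#' @param alpha level for the power column (default 0.05).
#' @param exact_max passed to [spearman_rho()].
#' @return Long data frame with columns `subfamily`, `variable`, `n`, `r_s`,
#'   `p`, `beta_power`, `eta`.
#' @export
correlation_battery <- function(subfamilies, eco, alpha = 0.05,
                                exact_max = 10) {
  responses <- intersect(c("rec_luxr", "luxr", "other", "total"),
                         names(subfamilies))
  vars <- setdiff(names(eco), "species_id")
  common <- intersect(subfamilies$species_id, eco$species_id)
  if (length(common) == 0) stop("no overlapping species", call. = FALSE)
  sf <- subfamilies[match(common, subfamilies$species_id), , drop = FALSE]
  ec <- eco[match(common, eco$species_id), , drop = FALSE]
  rows <- list()
  for (resp in responses) {
    for (v in vars) {
      y <- sf[[resp]]; x <- ec[[v]]
      ok <- complete.cases(x, y)
      n_cell <- sum(ok)
      if (n_cell < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          subfamily = resp, variable = v, n = n_cell, r_s = NA_real_,
          p = NA_real_, beta_power = NA_real_, eta = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      sp <- spearman_rho(x[ok], y[ok], exact_max = exact_max)
      beta <- if (!sp$degenerate && n_cell >= 4) {
        fisher_z_power(sp$r_s, n_cell, alpha)
      } else NA_real_
      eta <- tryCatch({
        e <- eta_coefficient(x[ok], y[ok])
        if (e$degenerate) NA_real_ else e$eta
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        subfamily = resp, variable = v, n = n_cell, r_s = sp$r_s, p = sp$p,
        beta_power = beta, eta = eta, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
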