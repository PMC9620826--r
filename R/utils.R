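`%||%` <- function(a, b) if (is.null(a)) b else a

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

.sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  switch(tolower(tools::file_ext(path)), csv = ",", "\t")
}

## parse ISO-8601 dates; timestamps are truncated to day resolution
.parse_dates <- function(x, col, allow_na = FALSE) {
  if (inherits(x, "Date")) return(data.table::as.IDate(x))
  xc <- as.character(x)
  d <- data.table::as.IDate(xc, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(xc) & nzchar(xc) & xc != "NA")
  if (length(bad) > 0L) {
    stop(sprintf("column '%s': unparseable date on data row(s) %s",
                 col, paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (!allow_na && anyNA(d)) {
    stop(sprintf("column '%s': missing dates on data row(s) %s",
                 col, paste(head(which(is.na(d)), 5L), collapse = ", ")),
         call. = FALSE)
  }
  d
}

.require_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.norm_icd <- function(x) toupper(trimws(x))

## Ordinary least squares via the QR decomposition, with pivoting so
## rank-deficient designs yield NA coefficients instead of an error.
.ols <- function(y, X) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  qx <- qr(X)
  r <- qx$rank
  if (n <= r) stop("not enough observations to fit model (n <= rank)",
                   call. = FALSE)
  coefs <- qr.coef(qx, y)
  res <- as.numeric(qr.resid(qx, y))
  df <- n - r
  s2 <- sum(res^2) / df
  se <- rep(NA_real_, ncol(X))
  names(se) <- colnames(X)
  Rm <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
  cov_unscaled <- chol2inv(Rm)
  se[qx$pivot[seq_len(r)]] <- sqrt(pmax(diag(cov_unscaled), 0) * s2)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  list(coef = coefs, se = se, t = tval, p = pval, df = df, rank = r,
       sigma = sqrt(s2), residuals = res, aliased = is.na(coefs))
}

#' Derive regression covariates from demographics
#'
#' Computes the standard covariate set used throughout the package: `sex`
#' (factor, levels sorted alphabetically so the reference level is the first
#' category), `age_first_visit` in years (taken from an `age_first_visit`
#' column if present, else derived as `(first_visit_date - birth_date) /
#' 365.25`), and `visit_span`, the elapsed time between first and last visit
#' in years.
#'
#' @param demos Validated demographics table.
#' @return A `data.table` with columns `person_id`, `sex`,
#'   `age_first_visit` (NA if underivable), and `visit_span`.
#' @export
derive_covariates <- function(demos) {
  age <- if ("age_first_visit" %in% names(demos)) {
    as.numeric(demos$age_first_visit)
  } else if ("birth_date" %in% names(demos)) {
    as.numeric(demos$first_visit_date - demos$birth_date) / 365.25
  } else {
    rep(NA_real_, nrow(demos))
  }
  data.table(
    person_id = demos$person_id,
    sex = factor(demos$sex, levels = sort(unique(as.character(demos$sex)))),
    age_first_visit = age,
    visit_span = as.numeric(demos$last_visit_date - demos$first_visit_date) /
      365.25
  )
}

## Model matrix (with intercept) for a covariate list, rows in demos order.
## Zero-variance covariates are dropped with a warning.
.covariate_matrix <- function(demos, covariates) {
  cov_dt <- derive_covariates(demos)
  if (length(covariates) == 0L) {
    X <- matrix(1, nrow = nrow(demos), ncol = 1L,
                dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  miss <- setdiff(covariates, names(cov_dt))
  if (length(miss) > 0L) {
    stop(sprintf("covariate(s) not derivable from demographics: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  keep <- character(0)
  for (cv in covariates) {
    v <- cov_dt[[cv]]
    if (anyNA(v)) {
      stop(sprintf("covariate '%s' has missing values (is birth_date or age_first_visit supplied?)",
                   cv), call. = FALSE)
    }
    nuniq <- data.table::uniqueN(v)
    if (nuniq < 2L) {
      warning(sprintf("covariate '%s' has zero variance; dropped", cv),
              call. = FALSE)
    } else {
      keep <- c(keep, cv)
    }
  }
  if (length(keep) == 0L) {
    return(matrix(1, nrow = nrow(demos), ncol = 1L,
                  dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(stats::reformulate(keep),
                      data = as.data.frame(cov_dt[, keep, with = FALSE]))
}
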