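#' Phenotype harmonization rules
#'
#' Bundles the settings of the harmonization pipeline: the tail quantiles
#' beyond which raw values are excluded as outliers, medication adjustment
#' rules, per-phenotype transforms, and the covariates regressed out before
#' rank-inverse-normalization.
#'
#' Medication rules follow the two patterns used for blood-pressure and
#' lipid phenotypes: `set_missing` discards the measurement of a treated
#' individual (systolic blood pressure, triglycerides, total cholesterol
#' under treatment), while `add_constant` shifts it by a fixed amount
#' (diastolic blood pressure + 10 mmHg under antihypertensives).
#'
#' @param lower_q,upper_q Exclusion quantiles (defaults 0.01 and 0.99);
#'   values strictly outside are masked.
#' @param med_rules List of `list(phenotype =, flag =, action =, constant =)`
#'   where `action` is `"set_missing"` or `"add_constant"`.
#' @param transforms Named character vector mapping phenotype name to
#'   `"log"` (natural log) or `"identity"`.
#' @param covariates Character vector of covariate columns used in the
#'   adjustment regression.
#' @param quantile_type Quantile definition passed to [stats::quantile()]
#'   (default 7, linear interpolation of order statistics).
#' @param normal_offsets Rank-normalization offsets: `"blom"`
#'   (\eqn{(r - 3/8)/(n + 1/4)}) or `"vdw"` (van der Waerden,
#'   \eqn{r/(n+1)}).
#' @param trim_first If `TRUE` (default) outlier trimming happens on raw
#'   values before medication rules; if `FALSE`, after.
#' @return An object of class `harmonization_rules`.
#' @export
harmonization_rules <- function(lower_q = 0.01, upper_q = 0.99,
                                med_rules = list(),
                                transforms = character(),
                                covariates = c("age", "sex", "study", "group"),
                                quantile_type = 7,
                                normal_offsets = c("blom", "vdw"),
                                trim_first = TRUE) {
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1)) {
    stop_field("lower_q/upper_q", "need 0 <= lower_q < upper_q <= 1")
  }
  for (r in med_rules) {
    if (!r$action %in% c("set_missing", "add_constant")) {
      stop_field("med_rules", "action must be set_missing or add_constant")
    }
    if (r$action == "add_constant" && !is.finite(r$constant %||% NA)) {
      stop_field("med_rules", "add_constant rules need a finite constant")
    }
  }
  structure(list(lower_q = lower_q, upper_q = upper_q, med_rules = med_rules,
                 transforms = transforms, covariates = covariates,
                 quantile_type = quantile_type,
                 normal_offsets = match.arg(normal_offsets),
                 trim_first = trim_first),
            class = "harmonization_rules")
}

#' Mask outlying phenotype values by pooled quantiles
#'
#' Marks values strictly below the `lower_q` quantile or strictly above the
#' `upper_q` quantile of the pooled non-missing vector. Quantiles use linear
#' interpolation of order statistics (type 7) by default.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param lower_q,upper_q Tail quantiles.
#' @param type Quantile type for [stats::quantile()].
#' @return Logical vector, `TRUE` where the value is excluded as an outlier.
#' @export
trim_outliers <- function(values, lower_q = 0.01, upper_q = 0.99, type = 7) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values missing; nothing to trim", call. = FALSE)
  if (sum(ok) < 10) stop("need >= 10 non-missing values to trim", call. = FALSE)
  q <- stats::quantile(values[ok], c(lower_q, upper_q), type = type, names = FALSE)
  out <- values < q[1] | values > q[2]
  out[is.na(out)] <- FALSE
  out
}

#' Apply medication adjustment rules to a phenotype
#'
#' @param values Numeric phenotype vector.
#' @param med_flags Named list (or data frame) of logical medication-use
#'   vectors, keyed by flag name.
#' @param med_rules Rules as in [harmonization_rules()]; only rules for
#'   `phenotype` are applied.
#' @param phenotype Name of the phenotype `values` belongs to.
#' @return Adjusted values; `set_missing` rules yield `NA` for flagged
#'   samples, `add_constant` rules shift flagged values.
#' @export
apply_medication_rules <- function(values, med_flags, med_rules,
                                   phenotype = "phenotype") {
  for (r in med_rules) {
    if (!identical(r$phenotype, phenotype)) next
    if (is.null(med_flags[[r$flag]])) {
      stop(sprintf("medication rule refers to unknown flag `%s`", r$flag),
           call. = FALSE)
    }
    flag <- med_flags[[r$flag]]
    if (!is.logical(flag)) stop_field("med_flags", "flags must be logical")
    flag[is.na(flag)] <- FALSE
    if (r$action == "set_missing") {
      values[flag] <- NA_real_
    } else {
      values[flag] <- values[flag] + r$constant
    }
  }
  values
}

#' Residualize a phenotype on covariates
#'
#' Ordinary least squares of the phenotype on the covariate design
#' (categorical covariates expanded to indicator contrasts), fitted on the
#' samples with non-missing phenotype; returns residuals there and `NA`
#' elsewhere.
#'
#' @param values Numeric phenotype vector.
#' @param covariates Data frame of covariates, one row per sample.
#' @return Numeric vector of residuals.
#' @export
adjust_covariates <- function(values, covariates) {
  ok <- !is.na(values)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values)) {
    stop_field("covariates", "must have one row per sample")
  }
  if (anyNA(covariates[ok, , drop = FALSE])) {
    stop("missing covariate values among included samples", call. = FALSE)
  }
  # drop single-level factors/characters so the design stays full rank by construction
  keep <- vapply(covariates, function(col) length(unique(col[ok])) > 1, TRUE)
  res <- rep(NA_real_, length(values))
  if (!any(keep)) {
    res[ok] <- values[ok] - mean(values[ok])
    return(res)
  }
  X <- stats::model.matrix(~ ., covariates[ok, keep, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res[ok] <- qr.resid(qrX, values[ok])
  res
}

#' Rank-inverse-normal transform
#'
#' Maps residual ranks through the standard-normal quantile function,
#' `qnorm((rank - c) / (n - 2c + 1))` with Blom offsets `c = 3/8` by default
#' (van der Waerden `c = 0` optional). Ties share the mean of their tied
#' ranks. Missing values stay missing.
#'
#' @param residuals Numeric vector.
#' @param offsets `"blom"` or `"vdw"`.
#' @return Numeric vector on the standard-normal scale.
#' @export
rank_normalize <- function(residuals, offsets = c("blom", "vdw")) {
  offsets <- match.arg(offsets)
  ok <- !is.na(residuals)
  n <- sum(ok)
  if (n < 3) stop("need >= 3 non-missing values to rank-normalize", call. = FALSE)
  r <- rank(residuals[ok], ties.method = "average")
  c0 <- if (offsets == "blom") 3 / 8 else 0
  out <- rep(NA_real_, length(residuals))
  out[ok] <- stats::qnorm((r - c0) / (n - 2 * c0 + 1))
  out
}

#' Harmonize a raw phenotype
#'
#' Full harmonization chain: outlier trimming by pooled quantiles,
#' medication adjustment, transform (natural log where configured),
#' covariate regression, and rank-inverse-normal transformation of the
#' residuals. The order of trimming versus medication rules follows
#' `rules$trim_first`.
#'
#' @param data Data frame holding the phenotype column, covariate columns,
#'   and any logical medication-flag columns.
#' @param phenotype Name of the phenotype column.
#' @param rules A [harmonization_rules()] object.
#' @return A list of class `adjusted_phenotype` with `values`
#'   (rank-normalized residuals, `NA` for excluded samples) and `mask`
#'   (per-sample status: `included`, `excluded_outlier`,
#'   `missing_medication`, or `missing_raw`).
#' @export
harmonize <- function(data, phenotype, rules = harmonization_rules()) {
  if (!inherits(rules, "harmonization_rules")) {
    stop_field("rules", "must be a harmonization_rules object")
  }
  if (!phenotype %in% names(data)) {
    stop(sprintf("phenotype `%s` not found in data", phenotype), call. = FALSE)
  }
  missing_cov <- setdiff(rules$covariates, names(data))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  for (r in rules$med_rules) {
    if (!identical(r$phenotype, phenotype)) next
    if (!r$flag %in% names(data)) {
      stop(sprintf("medication flag column `%s` not found", r$flag), call. = FALSE)
    }
  }
  v <- data[[phenotype]]
  mask <- rep("included", length(v))
  mask[is.na(v)] <- "missing_raw"

  do_trim <- function(v, mask) {
    out <- trim_outliers(v, rules$lower_q, rules$upper_q, rules$quantile_type)
    mask[out & mask == "included"] <- "excluded_outlier"
    v[out] <- NA_real_
    list(v, mask)
  }
  do_med <- function(v, mask) {
    before <- !is.na(v)
    v <- apply_medication_rules(v, data, rules$med_rules, phenotype)
    mask[before & is.na(v) & mask == "included"] <- "missing_medication"
    list(v, mask)
  }
  steps <- if (rules$trim_first) list(do_trim, do_med) else list(do_med, do_trim)
  for (f in steps) {
    st <- f(v, mask)
    v <- st[[1]]; mask <- st[[2]]
  }
  if (identical(unname(rules$transforms[phenotype]), "log")) {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    v <- log(v)
  }
  res <- adjust_covariates(v, data[rules$covariates])
  values <- rank_normalize(res, rules$normal_offsets)
  names(values) <- if (!is.null(data$id)) data$id else NULL
  structure(list(values = values,
                 mask = factor(mask, levels = c("included", "excluded_outlier",
                                                "missing_medication", "missing_raw"))),
            class = "adjusted_phenotype")
}
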